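## Expression-based reaction classification.
##
## The pipeline mirrors the flowchart used for growth-rate series data:
##   (A) per-feature log2 series across conditions (genes and proteins)
##   (B) restrict to metabolic genes
##   (C) features with fewer than `min_measurements` values go straight to
##       the invariant pool
##   (D) per-feature threshold regression test: OLS of log2 expression on
##       the condition value; the tested effect is the fitted change across
##       the full condition range, and the null is |effect| <= log2(T)
##       (a TREAT-style composite null), T = 1.5-fold by default
##   (E) gene and protein p-values merged, protein taking precedence
##   (F) FDR correction, differential = q below 0.2
##   (G) differential features signed by the regression slope
##   (H) gene states propagated to reactions through the GPR rules
## A simpler route classifies genes directly from log2 fold changes
## (|log2 fc| > 0.5850, i.e. 1.5-fold).

#' Construct an expression series
#'
#' @param feature_id gene or protein identifier (protein series share the
#'   gene locus id).
#' @param values expression values per condition (log2 scale unless stated
#'   otherwise downstream; missing allowed).
#' @param conditions ordered numeric condition labels (e.g. specific growth
#'   rates in 1/h).
#' @param kind \code{"gene"} or \code{"protein"}.
#' @return an object of class \code{expression_series}.
#' @export
expression_series <- function(feature_id, values, conditions,
                              kind = c("gene", "protein")) {
  kind <- match.arg(kind)
  if (length(values) != length(conditions)) {
    stop("values and conditions differ in length for ", feature_id)
  }
  structure(list(feature_id = feature_id, kind = kind,
                 conditions = as.numeric(conditions),
                 values = as.numeric(values)),
            class = "expression_series")
}

#' Preprocess expression series
#'
#' Removes features that do not map to metabolic genes, routes features
#' with too few measurements to the invariant pool, and ensures values are
#' on the log2 scale (transforming exactly once when raw).
#'
#' @param series list of [expression_series()] objects.
#' @param metabolic_genes character vector of gene ids present in the
#'   network's GPR rules.
#' @param min_measurements series with fewer non-missing values than this
#'   are declared invariant without testing.
#' @param values_are_log2 set \code{FALSE} for raw (positive) intensities,
#'   which are then log2-transformed.
#' @return list with \code{kept} (series list) and
#'   \code{dropped_to_invariant} (character vector of feature ids).
#' @export
preprocess <- function(series, metabolic_genes, min_measurements = 4,
                       values_are_log2 = TRUE) {
  kept <- list()
  invariant <- character(0)
  for (s in series) {
    if (!s$feature_id %in% metabolic_genes) next
    if (!values_are_log2) {
      if (any(s$values <= 0, na.rm = TRUE)) {
        stop("non-positive raw expression value for feature ", s$feature_id,
             "; cannot log2-transform")
      }
      s$values <- log2(s$values)
    }
    if (sum(!is.na(s$values)) < min_measurements) {
      invariant <- c(invariant, s$feature_id)
    } else {
      kept <- c(kept, list(s))
    }
  }
  list(kept = kept, dropped_to_invariant = unique(invariant))
}

#' Threshold regression test for one series
#'
#' Ordinary least squares of log2 expression on the condition value.  The
#' tested effect is the fitted change across the condition range,
#' \eqn{\Delta = slope \times (max(cond) - min(cond))}.  The p-value is for
#' the composite null \eqn{|\Delta| \le \log_2 T} against
#' \eqn{|\Delta| > \log_2 T}, computed as the sum of the two shifted tail
#' probabilities
#' \deqn{p = P(t_d > (|\hat\Delta|-\tau)/se) +
#'       P(t_d > (|\hat\Delta|+\tau)/se), \quad \tau = \log_2 T,}
#' capped at 1, with \eqn{d} the residual degrees of freedom (the same
#' form as limma's \code{treat} test, without its variance moderation
#' unless requested).  Under a point null \eqn{\Delta = 0} this approaches
#' 1, and at the boundary \eqn{|\Delta| = \tau} it is at least 1/2.  The
#' sign is the sign of the regression slope.
#'
#' Degenerate cases: zero condition variance gives sign 0 and p = 1 (no
#' direction is estimable); zero residual variance gives the limiting step
#' test (p = 0 if \eqn{|\hat\Delta| > \tau}, else 1).
#'
#' @param series an [expression_series()] (log2 values).
#' @param fold_threshold the fold-change threshold T (ratio scale).
#' @param s2_post,df_post optional moderated residual variance and degrees
#'   of freedom (used by the moderated pipeline); defaults to the
#'   per-feature OLS values.
#' @return list with \code{p_value}, \code{sign}, \code{effect}, \code{se},
#'   \code{df}, \code{s2} (residual variance), \code{slope}.
#' @export
threshold_regression_test <- function(series, fold_threshold = 1.5,
                                      s2_post = NULL, df_post = NULL) {
  ok <- !is.na(series$values)
  x <- series$conditions[ok]
  y <- series$values[ok]
  n <- length(y)
  if (n < 4) stop("threshold_regression_test needs >= 4 measurements (",
                  series$feature_id, " has ", n, ")")
  tau <- log2(fold_threshold)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0 || length(unique(x)) < 2) {
    return(list(p_value = 1, sign = 0, effect = 0, se = NA_real_,
                df = n - 2, s2 = NA_real_, slope = 0))
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  fit <- mean(y) + slope * (x - mean(x))
  df <- n - 2
  s2 <- sum((y - fit)^2) / df
  if (df < 3) {
    warning("only ", df, " residual degrees of freedom for ",
            series$feature_id, "; test performed anyway")
  }
  rng <- max(x) - min(x)
  effect <- slope * rng
  if (!is.null(s2_post)) s2 <- s2_post
  if (!is.null(df_post)) df <- df_post
  se <- sqrt(s2 / sxx) * rng
  if (se < .Machine$double.eps^0.5) {
    p <- if (abs(effect) > tau) 0 else 1
  } else {
    p <- min(1, stats::pt((abs(effect) - tau) / se, df, lower.tail = FALSE) +
                stats::pt((abs(effect) + tau) / se, df, lower.tail = FALSE))
  }
  list(p_value = p, sign = if (slope == 0) 0 else sign(slope),
       effect = effect, se = se, df = df, s2 = s2, slope = slope)
}

#' Run the threshold regression test over a set of series
#'
#' Optionally moderates the per-feature residual variances by shrinking
#' them toward the pooled residual variance with \code{prior_df} prior
#' degrees of freedom (an empirical-Bayes-style stabilisation for short
#' series), then recomputes the test.
#'
#' @param series list of [expression_series()].
#' @param fold_threshold fold-change threshold T.
#' @param moderate shrink residual variances toward their pooled value.
#' @param prior_df prior degrees of freedom for the shrinkage.
#' @return data.frame of differential calls: \code{feature_id},
#'   \code{p_value}, \code{q_value} (NA, filled by [estimate_fdr()]),
#'   \code{sign}, \code{source} (the series kind).
#' @export
threshold_regression_tests <- function(series, fold_threshold = 1.5,
                                       moderate = FALSE, prior_df = 4) {
  if (!length(series)) {
    return(data.frame(feature_id = character(0), p_value = numeric(0),
                      q_value = numeric(0), sign = numeric(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  fits <- lapply(series, threshold_regression_test,
                 fold_threshold = fold_threshold)
  if (moderate) {
    s2 <- vapply(fits, `[[`, numeric(1), "s2")
    df <- vapply(fits, `[[`, numeric(1), "df")
    okv <- is.finite(s2)
    s0 <- if (any(okv)) sum(s2[okv] * df[okv]) / sum(df[okv]) else 0
    fits <- lapply(seq_along(series), function(i) {
      if (!okv[i]) return(fits[[i]])
      s2p <- (prior_df * s0 + df[i] * s2[i]) / (prior_df + df[i])
      threshold_regression_test(series[[i]], fold_threshold,
                                s2_post = s2p, df_post = df[i] + prior_df)
    })
  }
  data.frame(
    feature_id = vapply(series, `[[`, character(1), "feature_id"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    q_value = NA_real_,
    sign = vapply(fits, `[[`, numeric(1), "sign"),
    source = vapply(series, `[[`, character(1), "kind"),
    stringsAsFactors = FALSE)
}

#' Merge gene- and protein-level differential calls
#'
#' Protein abundance is closer to the metabolic phenotype than transcript
#' abundance, so where both levels were tested the protein call (p-value
#' and sign) is taken wholesale; otherwise the gene call; features with
#' neither are non-differential by construction (sign 0, source
#' \code{"none"}).
#'
#' @param gene_calls,protein_calls call data.frames from
#'   [threshold_regression_tests()].
#' @param all_features optional character vector; features listed here but
#'   present in neither call set are appended with source \code{"none"}.
#' @return one call data.frame with a single row per feature.
#' @export
merge_gene_protein <- function(gene_calls, protein_calls,
                               all_features = NULL) {
  prot <- protein_calls[!duplicated(protein_calls$feature_id), , drop = FALSE]
  gene <- gene_calls[!duplicated(gene_calls$feature_id), , drop = FALSE]
  gene_only <- gene[!(gene$feature_id %in% prot$feature_id), , drop = FALSE]
  out <- rbind(prot, gene_only)
  if (!is.null(all_features)) {
    missing <- setdiff(all_features, out$feature_id)
    if (length(missing)) {
      out <- rbind(out, data.frame(feature_id = missing, p_value = NA_real_,
                                   q_value = NA_real_, sign = 0,
                                   source = "none",
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Estimate false discovery rates
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param method \code{"BH"} (Benjamini-Hochberg, default) or
#'   \code{"grenander"}, a tail-area FDR from the Grenander (least concave
#'   majorant) estimate of the p-value distribution with the null
#'   proportion taken from its terminal slope.
#' @return vector of q-values.
#' @export
estimate_fdr <- function(p_values, method = c("BH", "grenander")) {
  method <- match.arg(method)
  p <- p_values
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (method == "BH") return(stats::p.adjust(p, method = "BH"))
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  q[ok] <- grenander_fdr(p[ok])
  q
}

## Tail-area FDR from the least concave majorant (Grenander estimator) of
## the p-value ECDF: Fdr(p) = eta0 * p / F(p), with the null proportion
## eta0 estimated from the upper tail of the p-value distribution.
grenander_fdr <- function(p) {
  n <- length(p)
  if (n == 1L) return(pmin(1, p))
  sp <- sort(unique(p))
  Fn <- vapply(sp, function(t) mean(p <= t), numeric(1))
  px <- c(0, sp); py <- c(0, Fn)
  if (sp[length(sp)] < 1) { px <- c(px, 1); py <- c(py, 1) }
  ## upper (concave) hull by monotone chain
  hull <- c(1L)
  for (k in 2:length(px)) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      cross <- (px[b] - px[a]) * (py[k] - py[a]) -
               (py[b] - py[a]) * (px[k] - px[a])
      if (cross >= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, k)
  }
  hx <- px[hull]; hy <- py[hull]
  ## null proportion from the upper tail (nulls dominate p > 1/2)
  eta0 <- min(1, mean(p > 0.5) / 0.5)
  Fhat <- stats::approx(hx, hy, xout = p, rule = 2)$y
  q <- pmin(1, ifelse(Fhat > 0, eta0 * p / Fhat, 1))
  ## tail-area FDR is non-decreasing in p
  ord <- order(p)
  q[ord] <- cummax(q[ord])
  q
}

#' Call differential features
#'
#' @param calls call data.frame with populated \code{q_value}.
#' @param fdr_cut features with q strictly below this (and a nonzero sign)
#'   are differential.
#' @return named character vector: feature id -> \code{"up"},
#'   \code{"down"} or \code{"invariant"}.
#' @export
call_differential <- function(calls, fdr_cut = 0.2) {
  st <- ifelse(!is.na(calls$q_value) & calls$q_value < fdr_cut &
                 calls$sign > 0, "up",
               ifelse(!is.na(calls$q_value) & calls$q_value < fdr_cut &
                        calls$sign < 0, "down", "invariant"))
  stats::setNames(st, calls$feature_id)
}

#' Classify genes by log2 fold change
#'
#' The simple route: genes with log2 fold change above \code{cutoff}
#' (1.5-fold by default, log2 = 0.5850) are up, below \code{-cutoff} down,
#' anything else (including missing) invariant.
#'
#' @param log2fc named numeric vector of per-gene log2 fold changes.
#' @param cutoff threshold on the log2 scale.
#' @return named character vector of gene states.
#' @export
classify_by_fold_change <- function(log2fc, cutoff = 0.5850) {
  st <- ifelse(is.na(log2fc), "invariant",
               ifelse(log2fc > cutoff, "up",
                      ifelse(log2fc < -cutoff, "down", "invariant")))
  stats::setNames(st, names(log2fc))
}

#' Map gene states onto reactions through GPR rules
#'
#' Gene states are coded up = +1, invariant = 0, down = -1 (missing genes
#' count 0); AND nodes take the minimum over children, OR nodes the
#' maximum.  A reaction is H if its rule evaluates to +1, L if -1, and M
#' otherwise (including reactions without a rule).  Both members of a split
#' reversible pair share the same GPR and hence the same state.
#'
#' @param net an \code{icfp_network}.
#' @param states named character vector of gene states
#'   (\code{"up"}/\code{"down"}/\code{"invariant"}).
#' @return named character vector: reaction id -> \code{"H"}, \code{"M"} or
#'   \code{"L"}.
#' @export
map_to_reactions <- function(net, states) {
  num <- c(up = 1, invariant = 0, down = -1)[states]
  names(num) <- names(states)
  if (anyNA(num)) stop("unknown gene state: ",
                       paste(unique(states[is.na(num)]), collapse = ", "))
  out <- vapply(net$reactions, function(r) {
    v <- eval_gpr(r$gpr_tree, num)
    if (v > 0) "H" else if (v < 0) "L" else "M"
  }, character(1))
  stats::setNames(out, reaction_ids(net))
}

#' Genes appearing in a network's GPR rules
#' @param net an \code{icfp_network}.
#' @return character vector of gene ids.
#' @export
network_genes <- function(net) {
  unique(unlist(lapply(net$reactions, function(r) gpr_genes(r$gpr_tree))))
}

#' Classify reactions from expression data
#'
#' Front end for both classification routes.  The series route runs the
#' full flowchart (preprocess, threshold regression, gene/protein merge,
#' FDR, sign); the fold-change route thresholds per-gene log2 fold changes
#' directly.  Either way gene states are propagated to reactions through
#' the GPR rules.
#'
#' @param net an \code{icfp_network}.
#' @param series list of [expression_series()] (series route).
#' @param log2fc named numeric vector (fold-change route).
#' @param fold_threshold TREAT threshold T (ratio), series route.
#' @param fdr_cut FDR cut for differential calls, series route.
#' @param fc_cutoff log2 cutoff, fold-change route.
#' @param min_measurements minimum non-missing values per tested series.
#' @param values_are_log2 whether series values are already log2.
#' @param fdr_method passed to [estimate_fdr()].
#' @param moderate,prior_df variance moderation, see
#'   [threshold_regression_tests()].
#' @param metabolic_genes gene universe; defaults to the genes named in the
#'   network's GPR rules.
#' @return object of class \code{reaction_classification}: a data.frame
#'   with columns \code{reaction_id}, \code{state}, \code{genes},
#'   \code{source}; attributes carry the gene states, merged calls and the
#'   flowchart stage counts.
#' @export
classify_reactions <- function(net, series = NULL, log2fc = NULL,
                               fold_threshold = 1.5, fdr_cut = 0.2,
                               fc_cutoff = 0.5850, min_measurements = 4,
                               values_are_log2 = TRUE, fdr_method = "BH",
                               moderate = FALSE, prior_df = 4,
                               metabolic_genes = NULL) {
  if (is.null(series) == is.null(log2fc)) {
    stop("supply exactly one of `series` (series route) or `log2fc` ",
         "(fold-change route)")
  }
  if (is.null(metabolic_genes)) metabolic_genes <- network_genes(net)
  counts <- list()
  if (!is.null(log2fc)) {
    gene_states <- classify_by_fold_change(log2fc, cutoff = fc_cutoff)
    gene_states <- gene_states[names(gene_states) %in% metabolic_genes]
    calls <- NULL
    counts$route <- "fold_change"
  } else {
    counts$route <- "series"
    counts$n_series_input <- length(series)
    pp <- preprocess(series, metabolic_genes,
                     min_measurements = min_measurements,
                     values_are_log2 = values_are_log2)
    counts$n_series_metabolic <- length(pp$kept) +
      length(pp$dropped_to_invariant)
    counts$n_dropped_few_measurements <- length(pp$dropped_to_invariant)
    kinds <- vapply(pp$kept, `[[`, character(1), "kind")
    gene_calls <- threshold_regression_tests(
      pp$kept[kinds == "gene"], fold_threshold, moderate, prior_df)
    protein_calls <- threshold_regression_tests(
      pp$kept[kinds == "protein"], fold_threshold, moderate, prior_df)
    calls <- merge_gene_protein(gene_calls, protein_calls,
                                all_features = metabolic_genes)
    counts$n_pvalues_merged <- sum(calls$source != "none")
    tested <- calls$source != "none"
    calls$q_value[tested] <- estimate_fdr(calls$p_value[tested],
                                          method = fdr_method)
    gene_states <- call_differential(calls, fdr_cut = fdr_cut)
    gene_states[calls$feature_id %in% pp$dropped_to_invariant] <- "invariant"
    counts$n_differential <- sum(gene_states != "invariant")
  }
  counts$n_up <- sum(gene_states == "up")
  counts$n_down <- sum(gene_states == "down")
  rx_states <- map_to_reactions(net, gene_states)
  counts$n_H <- sum(rx_states == "H")
  counts$n_M <- sum(rx_states == "M")
  counts$n_L <- sum(rx_states == "L")
  df <- data.frame(
    reaction_id = names(rx_states),
    state = unname(rx_states),
    genes = vapply(net$reactions, function(r) {
      paste(gpr_genes(r$gpr_tree), collapse = ";")
    }, character(1)),
    source = vapply(net$reactions, function(r) {
      g <- gpr_genes(r$gpr_tree)
      if (!length(g)) return("none")
      if (!is.null(calls)) {
        src <- calls$source[match(g, calls$feature_id)]
        src <- src[!is.na(src) & src != "none"]
        if (!length(src)) "none" else paste(sort(unique(src)), collapse = "+")
      } else "fold_change"
    }, character(1)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("reaction_classification", "data.frame"),
            gene_states = gene_states, calls = calls, counts = counts)
}

#' @export
print.reaction_classification <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("Reaction classification (", cnt$route, " route): |H| = ", cnt$n_H,
      ", |M| = ", cnt$n_M, ", |L| = ", cnt$n_L, "\n", sep = "")
  cat("Gene states: ", cnt$n_up, " up, ", cnt$n_down, " down\n", sep = "")
  if (!is.null(cnt$n_pvalues_merged)) {
    cat("Flowchart: ", cnt$n_series_input, " series in, ",
        cnt$n_series_metabolic, " metabolic, ",
        cnt$n_dropped_few_measurements, " with too few measurements, ",
        cnt$n_pvalues_merged, " merged p-values, ",
        cnt$n_differential, " differential\n", sep = "")
  }
  NextMethod()
  invisible(x)
}

#' Write a classification to TSV
#' @param x a \code{reaction_classification}.
#' @param path output file.
#' @export
write_classification <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
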