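# Small hand-built networks used across the suite.

# linear chain src -> m2 -> ... -> tgt of 1:1 conversions; states per reaction
chain_network <- function(n = 3, states = NULL) {
  ids <- c("src", if (n > 1) paste0("m", seq_len(n - 1)), "tgt")
  mets <- data.frame(id = ids, name = ids,
                     is_internal = !(ids %in% c("src", "tgt")),
                     in_medium = ids == "src",
                     stringsAsFactors = FALSE)
  reactions <- lapply(seq_len(n), function(i) {
    list(id = paste0("c", i),
         stoich = stats::setNames(c(-1, 1), c(ids[i], ids[i + 1])),
         reversible = FALSE, gpr = paste0("g", i))
  })
  arcs <- data.frame(reaction = paste0("c", seq_len(n)),
                     substrate = ids[seq_len(n)],
                     product = ids[seq_len(n) + 1],
                     stringsAsFactors = FALSE)
  metabolic_network(mets, reactions, arcs)
}

# two disjoint simple routes src -> tgt: lengths 2 (via a) and 3 (via b1, b2)
two_path_network <- function() {
  ids <- c("src", "a", "b1", "b2", "tgt")
  mets <- data.frame(id = ids, name = ids,
                     is_internal = !(ids %in% c("src", "tgt")),
                     in_medium = ids == "src",
                     stringsAsFactors = FALSE)
  rx <- function(id, from, to) {
    list(id = id, stoich = stats::setNames(c(-1, 1), c(from, to)),
         reversible = FALSE, gpr = "")
  }
  reactions <- list(rx("ra1", "src", "a"), rx("ra2", "a", "tgt"),
                    rx("rb1", "src", "b1"), rx("rb2", "b1", "b2"),
                    rx("rb3", "b2", "tgt"))
  arcs <- data.frame(
    reaction = c("ra1", "ra2", "rb1", "rb2", "rb3"),
    substrate = c("src", "a", "src", "b1", "b2"),
    product = c("a", "tgt", "b1", "b2", "tgt"),
    stringsAsFactors = FALSE)
  metabolic_network(mets, reactions, arcs)
}

tuple_of <- function(path) round(unname(path$staged_objective), 6)
oracle_tuple <- function(entry) round(c(entry$V1, entry$V2, entry$length), 6)
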