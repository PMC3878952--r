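<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_chain" name="Three-step linear conversion chain">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="glc_e" name="glucose (external)" compartment="c"
               boundaryCondition="true" constant="false"
               hasOnlySubstanceUnits="false"/>
      <species id="g6p_c" name="glucose 6-phosphate" compartment="c"
               boundaryCondition="false" constant="false"
               hasOnlySubstanceUnits="false"/>
      <species id="f6p_c" name="fructose 6-phosphate" compartment="c"
               boundaryCondition="false" constant="false"
               hasOnlySubstanceUnits="false"/>
      <species id="pyr_e" name="pyruvate (external)" compartment="c"
               boundaryCondition="true" constant="false"
               hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_b0001" fbc:label="b0001"/>
      <fbc:geneProduct fbc:id="G_b0002" fbc:label="b0002"/>
      <fbc:geneProduct fbc:id="G_b0003" fbc:label="b0003"/>
      <fbc:geneProduct fbc:id="G_b0004" fbc:label="b0004"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="HEX" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="g6p_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_b0001"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="PGI" reversible="true" fast="false">
        <listOfReactants>
          <speciesReference species="g6p_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="f6p_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_b0002"/>
            <fbc:and>
              <fbc:geneProductRef fbc:geneProduct="G_b0003"/>
              <fbc:geneProductRef fbc:geneProduct="G_b0004"/>
            </fbc:and>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="LOWER" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="f6p_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="pyr_e" stoichiometry="2" constant="true"/>
        </listOfProducts>
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>GENE_ASSOCIATION: b0002 and b0003</p>
          </body>
        </notes>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
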