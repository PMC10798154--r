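<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="synthmodel" name="synthetic model">
    <listOfCompartments>
      <compartment id="C1" name="compartment C1" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="S1" name="species S1" compartment="C1" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="S2" name="species S2" compartment="C1" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R1" name="reaction R1" reversible="false">
        <listOfReactants>
          <speciesReference species="S1" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="S2" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
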