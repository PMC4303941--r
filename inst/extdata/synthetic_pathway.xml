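<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic KGML-subset pathway for tests and examples (not a KEGG export).
     Node "names" are accession lists; includes one unsupported relation
     subtype (binding) and one 2-cycle to exercise preprocessing. -->
<pathway name="path:syn00001" title="synthetic demo pathway">
  <entry id="1" name="SYN0001 SYN0002" type="gene"/>
  <entry id="2" name="SYN0101" type="gene"/>
  <entry id="3" name="SYN0201 SYN0202 SYN0203" type="gene"/>
  <entry id="4" name="SYN0301" type="gene"/>
  <entry id="5" name="SYN0401" type="gene"/>
  <relation entry1="1" entry2="2" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="2" entry2="3" type="PPrel">
    <subtype name="inhibition" value="--|"/>
  </relation>
  <relation entry1="3" entry2="4" type="PPrel">
    <subtype name="expression" value="--&gt;"/>
  </relation>
  <relation entry1="4" entry2="3" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="1" entry2="5" type="PPrel">
    <subtype name="binding" value="---"/>
  </relation>
</pathway>
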