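# Synthetic sample knowledge assembly in BEL Script, constructed for this
# package's documentation and tests. It mixes statements inside the supported
# minimal dialect with a handful of full-BEL constructs outside it (namespace
# definitions, nested terms, translocations), so that lenient ingestion can
# be demonstrated: out-of-dialect lines are counted and skipped, in-dialect
# statements are kept.

DEFINE NAMESPACE HGNC AS URL "http://example.org/hgnc.belns"
DEFINE ANNOTATION Subgraph AS LIST {"Gaba subgraph", "Adenosine subgraph"}

SET Citation = {"PubMed", "20000001"}
SET Evidence = "Carbamazepine activates the GABA receptor family."
SET Subgraph = "Gaba subgraph"
a(CHEBI:carbamazepine) increases p(HGNC:GABRA1)
p(HGNC:GABRA1) increases bp(GO:"inhibitory synaptic transmission")
bp(GO:"inhibitory synaptic transmission") decreases path(MESH:Seizures)

SET Citation = {"PubMed", "20000002"}
SET Evidence = "EGR1 drives transcription of GABA receptor subunits."
p(HGNC:EGR1) increases r(HGNC:GABRA1)
p(HGNC:EGR1) increases p(HGNC:PSEN2)
p(HGNC:PSEN2, pmod(P, S, 327)) increases path(MESH:Seizures)

SET Citation = {"PubMed", "20000003"}
SET Subgraph = "Adenosine subgraph"
a(CHEBI:carbamazepine) increases a(CHEBI:adenosine)
a(CHEBI:adenosine) increases p(HGNC:ADORA1)
complex(p(HGNC:ADORA1), p(HGNC:ADORA3)) decreases bp(GO:"glutamatergic signaling")
tloc(p(HGNC:SLC29A1), GO:"plasma membrane", GO:"cytoplasm") decreases a(CHEBI:adenosine)
p(HGNC:ADORA1) decreases bp(GO:"glutamatergic signaling")
UNSET ALL
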