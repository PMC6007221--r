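{
  "entities": [
    {
      "function": "abundance",
      "namespace": "CHEBI",
      "name": "adenosine"
    },
    {
      "function": "bioprocess",
      "namespace": "GO",
      "name": "inhibitory synaptic transmission"
    },
    {
      "function": "bioprocess",
      "namespace": "GO",
      "name": "neuronal action potential"
    },
    {
      "function": "pathology",
      "namespace": "MESH",
      "name": "Epilepsy"
    },
    {
      "function": "protein",
      "namespace": "HGNC",
      "name": "ADORA1"
    },
    {
      "function": "protein",
      "namespace": "HGNC",
      "name": "GABRA1"
    },
    {
      "function": "protein",
      "namespace": "HGNC",
      "name": "SCN1A"
    }
  ],
  "relations": [
    {
      "subject": {
        "function": "protein",
        "namespace": "HGNC",
        "name": "GABRA1"
      },
      "relation": "increases",
      "object": {
        "function": "bioprocess",
        "namespace": "GO",
        "name": "inhibitory synaptic transmission"
      },
      "citation": {
        "type": "PubMed",
        "identifier": "1"
      },
      "subgraphs": ["Gaba subgraph"]
    },
    {
      "subject": {
        "function": "protein",
        "namespace": "HGNC",
        "name": "SCN1A"
      },
      "relation": "decreases",
      "object": {
        "function": "bioprocess",
        "namespace": "GO",
        "name": "neuronal action potential"
      },
      "citation": {
        "type": "PubMed",
        "identifier": "1"
      },
      "subgraphs": ["Sodium channel subgraph"]
    },
    {
      "subject": {
        "function": "protein",
        "namespace": "HGNC",
        "name": "ADORA1"
      },
      "relation": "increases",
      "object": {
        "function": "abundance",
        "namespace": "CHEBI",
        "name": "adenosine"
      },
      "citation": {
        "type": "PubMed",
        "identifier": "2"
      },
      "subgraphs": ["Adenosine subgraph"]
    },
    {
      "subject": {
        "function": "abundance",
        "namespace": "CHEBI",
        "name": "adenosine"
      },
      "relation": "increases",
      "object": {
        "function": "bioprocess",
        "namespace": "GO",
        "name": "inhibitory synaptic transmission"
      },
      "citation": {
        "type": "PubMed",
        "identifier": "3"
      },
      "subgraphs": ["Adenosine subgraph"]
    },
    {
      "subject": {
        "function": "protein",
        "namespace": "HGNC",
        "name": "SCN1A"
      },
      "relation": "association",
      "object": {
        "function": "pathology",
        "namespace": "MESH",
        "name": "Epilepsy"
      },
      "citation": {
        "type": "PubMed",
        "identifier": "3"
      },
      "subgraphs": ["Sodium channel subgraph"]
    }
  ],
  "subgraph_inventory": ["Adenosine subgraph", "Gaba subgraph", "Sodium channel subgraph"]
}
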