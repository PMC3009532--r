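{
  "schema_version": "1.0",
  "mode": "promoter",
  "params": {
    "promoterFlank": 500,
    "transcriptFlank": 500,
    "tcGeneWindow": 500,
    "neighborhoodHalfWidth": 1000000,
    "sharedTssTolerance": 100,
    "shapeQuantiles": [0.1, 0.9],
    "sharpWidthMax": 4,
    "maxAnchorLoci": 2,
    "minAnchorWidth": 10
  },
  "anchor_colors": {
    "one_to_one": "gray",
    "one_to_two": "blue"
  },
  "ref": {
    "assembly": "genomeA",
    "region": {
      "seq": "chrA",
      "start": 10402,
      "end": 12601,
      "name": "gA01"
    },
    "genes": [
      {
        "gene_id": "gA01",
        "name": "gA01",
        "synonyms": "",
        "transcripts": [
          {
            "tx_id": "gA01.t1",
            "seq": "chrA",
            "strand": "-",
            "exons": [
              {
                "start": 9073,
                "end": 9252
              },
              {
                "start": 9853,
                "end": 10052
              },
              {
                "start": 10753,
                "end": 10902
              }
            ]
          },
          {
            "tx_id": "gA01.t2",
            "seq": "chrA",
            "strand": "-",
            "exons": [
              {
                "start": 10273,
                "end": 10452
              },
              {
                "start": 11053,
                "end": 11252
              },
              {
                "start": 11953,
                "end": 12102
              }
            ]
          }
        ]
      }
    ],
    "tag_clusters": [
      {
        "seq": "chrA",
        "start": 10902,
        "end": 10902,
        "strand": "-",
        "n_tags": 1,
        "total_count": 42,
        "tpm": 92307.6923076923,
        "rep_pos": 10902,
        "shape": "sharp"
      },
      {
        "seq": "chrA",
        "start": 12102,
        "end": 12102,
        "strand": "-",
        "n_tags": 1,
        "total_count": 47,
        "tpm": 103296.703296703,
        "rep_pos": 12102,
        "shape": "sharp"
      }
    ]
  },
  "target": {
    "assembly": "genomeB",
    "region": {
      "seq": "chrB",
      "start": 20402,
      "end": 22601,
      "name": "gA01o"
    },
    "genes": [
      {
        "gene_id": "gA01o",
        "name": "gA01o",
        "synonyms": "",
        "transcripts": [
          {
            "tx_id": "gA01.t1o",
            "seq": "chrB",
            "strand": "-",
            "exons": [
              {
                "start": 19073,
                "end": 19252
              },
              {
                "start": 19853,
                "end": 20052
              },
              {
                "start": 20753,
                "end": 20902
              }
            ]
          },
          {
            "tx_id": "gA01.t2o",
            "seq": "chrB",
            "strand": "-",
            "exons": [
              {
                "start": 20273,
                "end": 20452
              },
              {
                "start": 21053,
                "end": 21252
              },
              {
                "start": 21953,
                "end": 22102
              }
            ]
          }
        ]
      }
    ],
    "tag_clusters": [
      {
        "seq": "chrB",
        "start": 20902,
        "end": 20902,
        "strand": "-",
        "n_tags": 1,
        "total_count": 18,
        "tpm": 50279.3296089385,
        "rep_pos": 20902,
        "shape": "sharp"
      },
      {
        "seq": "chrB",
        "start": 21900,
        "end": 21900,
        "strand": "-",
        "n_tags": 1,
        "total_count": 35,
        "tpm": 97765.3631284916,
        "rep_pos": 21900,
        "shape": "sharp"
      }
    ]
  },
  "anchors": [
    {
      "ref_seq": "chrA",
      "ref_start": 10402,
      "ref_end": 12601,
      "target_seq": "chrB",
      "target_start": 20402,
      "target_end": 22601,
      "multiplicity": "one_to_one",
      "chain_id": "1",
      "score": 9000,
      "orientation": "same",
      "color": "gray"
    }
  ],
  "annotations": {
    "geneRef": "gA01",
    "geneTarget": "gA01o",
    "promoterCentersRef": [10902, 12102],
    "promoterCentersTarget": [20902, 22102],
    "sharedTss": [
      {
        "ref_tc": 1,
        "target_tc": 1,
        "ref_pos": 10902,
        "target_pos": 20902,
        "mapped_distance": 0
      }
    ],
    "turnoverRef": 2,
    "turnoverTarget": 2
  }
}
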