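{
  "version": "1.0",
  "provenance": "field calibration, temperate degraded-vegetation survey; coefficients reproduced digit-for-digit from the printed equations",
  "stepwise": [
    {
      "id": "D_N", "nutrient": "N", "family": "D", "intercept": 21.6,
      "terms": [
        {"label": "D_937", "band": 937, "coefficient": -2186.079},
        {"label": "D_818", "band": 818, "coefficient": 11429.702},
        {"label": "D_938", "band": 938, "coefficient": -1249.616},
        {"label": "D_623", "band": 623, "coefficient": 22063.134}
      ],
      "fit_r2": 0.762, "adj_r2": 0.712
    },
    {
      "id": "D_P", "nutrient": "P", "family": "D", "intercept": 190.487,
      "terms": [
        {"label": "D_424", "band": 424, "coefficient": 91712.256},
        {"label": "D_416", "band": 416, "coefficient": -54522.874},
        {"label": "D_458", "band": 458, "coefficient": -148213.752},
        {"label": "D_902", "band": 902, "coefficient": 7056.261}
      ],
      "fit_r2": 0.762, "adj_r2": 0.711
    },
    {
      "id": "D_K", "nutrient": "K", "family": "D", "intercept": 61.532,
      "terms": [
        {"label": "D_919", "band": 919, "coefficient": 12691.028},
        {"label": "D_483", "band": 483, "coefficient": 41079.969},
        {"label": "D_457", "band": 457, "coefficient": 37268.512}
      ],
      "fit_r2": 0.793, "adj_r2": 0.749
    },
    {
      "id": "ND_N", "nutrient": "N", "family": "ND", "intercept": -6.087,
      "terms": [
        {"label": "ND_657", "band": 657, "coefficient": -4782.424},
        {"label": "ND_633", "band": 633, "coefficient": -7728.328},
        {"label": "ND_652", "band": 652, "coefficient": 3661.663}
      ],
      "fit_r2": 0.776, "adj_r2": 0.729
    },
    {
      "id": "ND_P", "nutrient": "P", "family": "ND", "intercept": 181.13,
      "terms": [
        {"label": "ND_424", "band": 424, "coefficient": 689.047},
        {"label": "ND_828", "band": 828, "coefficient": 55951.851},
        {"label": "ND_427", "band": 427, "coefficient": -4876.394}
      ],
      "fit_r2": 0.717, "adj_r2": 0.679
    },
    {
      "id": "ND_K", "nutrient": "K", "family": "ND", "intercept": 61.47,
      "terms": [
        {"label": "ND_919", "band": 919, "coefficient": 9721.848},
        {"label": "ND_457", "band": 457, "coefficient": 3614.272},
        {"label": "ND_483", "band": 483, "coefficient": 2891.555}
      ],
      "fit_r2": 0.855, "adj_r2": 0.824
    },
    {
      "id": "FD_N", "nutrient": "N", "family": "FD", "intercept": 4.874,
      "terms": [
        {"label": "FD_624", "band": 624, "coefficient": -69663.699},
        {"label": "FD_668", "band": 668, "coefficient": 197983.562},
        {"label": "FD_842", "band": 842, "coefficient": 28017.123}
      ],
      "fit_r2": 0.876, "adj_r2": 0.850
    },
    {
      "id": "FD_P", "nutrient": "P", "family": "FD", "intercept": 131.451,
      "terms": [
        {"label": "FD_839", "band": 839, "coefficient": -196845.744},
        {"label": "FD_819", "band": 819, "coefficient": 46413.765},
        {"label": "FD_421", "band": 421, "coefficient": 25813.846}
      ],
      "fit_r2": 0.810, "adj_r2": 0.769
    },
    {
      "id": "FD_K", "nutrient": "K", "family": "FD", "intercept": 105.882,
      "terms": [
        {"label": "FD_900", "band": 900, "coefficient": -64164.877},
        {"label": "FD_646", "band": 646, "coefficient": -43285.081},
        {"label": "FD_916", "band": 916, "coefficient": -26455.909}
      ],
      "fit_r2": 0.795, "adj_r2": 0.751
    },
    {
      "id": "FDD_N", "nutrient": "N", "family": "FDD", "intercept": 11.575,
      "terms": [
        {"label": "FDD_821", "band": 821, "coefficient": -36198.245},
        {"label": "FDD_468", "band": 468, "coefficient": 38033.1},
        {"label": "FDD_657", "band": 657, "coefficient": -26486.514}
      ],
      "fit_r2": 0.879, "adj_r2": 0.854
    },
    {
      "id": "FDD_P", "nutrient": "P", "family": "FDD", "intercept": 142.191,
      "terms": [
        {"label": "FDD_485", "band": 485, "coefficient": -132036.035},
        {"label": "FDD_664", "band": 664, "coefficient": 288047.809},
        {"label": "FDD_933", "band": 933, "coefficient": -71641.791}
      ],
      "fit_r2": 0.838, "adj_r2": 0.803
    },
    {
      "id": "FDD_K", "nutrient": "K", "family": "FDD", "intercept": 98.683,
      "terms": [
        {"label": "FDD_835", "band": 835, "coefficient": 83049.321},
        {"label": "FDD_731", "band": 731, "coefficient": 64569.839}
      ],
      "fit_r2": 0.659, "adj_r2": 0.631
    }
  ],
  "single_index": [
    {"id": "RES_N", "nutrient": "N", "index": "RES",
     "slope": -786.75, "intercept": 13.733, "r2": 0.1373},
    {"id": "RES_P", "nutrient": "P", "index": "RES",
     "slope": -6221.3, "intercept": 146.95, "r2": 0.09},
    {"id": "RES_K", "nutrient": "K", "index": "RES",
     "slope": -7846.6, "intercept": 131.48, "r2": 0.169},
    {"id": "DVI_N", "nutrient": "N", "index": "DVI",
     "slope": -0.0017, "intercept": 32.711, "r2": 0.050},
    {"id": "DVI_P", "nutrient": "P", "index": "DVI",
     "slope": -0.0024, "intercept": 181.27, "r2": 0.014},
    {"id": "DVI_K", "nutrient": "K", "index": "DVI",
     "slope": -0.0028, "intercept": 95.466, "r2": 0.06},
    {"id": "FD730-570_N", "nutrient": "N", "index": "FD730-570",
     "slope": -440.44, "intercept": 10.251, "r2": 0.053},
    {"id": "FD730-570_P", "nutrient": "P", "index": "FD730-570",
     "slope": -4351.8, "intercept": 126.87, "r2": 0.054},
    {"id": "FD730-570_K", "nutrient": "K", "index": "FD730-570",
     "slope": -7213.4, "intercept": 120.97, "r2": 0.177}
  ]
}
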