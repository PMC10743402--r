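{
  "protein": "otoferlin (OTOF long isoform)",
  "protein_length": 1979,
  "synthetic_layers": ["comp_bias", "coiled_coil", "exons"],
  "notes": "domains and regions are literature-reported coordinates; comp_bias, coiled_coil and the exon partition are SYNTHETIC placeholder intervals (real coordinates are not bundled); supply your own config to override any layer",
  "domains": [
    {
      "start": 1,
      "end": 98,
      "code": 1,
      "name": "C2-1"
    },
    {
      "start": 236,
      "end": 357,
      "code": 2,
      "name": "C2-2"
    },
    {
      "start": 400,
      "end": 531,
      "code": 3,
      "name": "C2-3"
    },
    {
      "start": 944,
      "end": 1069,
      "code": 4,
      "name": "C2-4"
    },
    {
      "start": 1115,
      "end": 1242,
      "code": 5,
      "name": "C2-5"
    },
    {
      "start": 1464,
      "end": 1593,
      "code": 6,
      "name": "C2-6"
    },
    {
      "start": 1714,
      "end": 1865,
      "code": 7,
      "name": "C2-7"
    }
  ],
  "regions": [
    {
      "start": 128,
      "end": 171,
      "code": 1,
      "name": "IDR-1"
    },
    {
      "start": 642,
      "end": 694,
      "code": 2,
      "name": "IDR-2"
    },
    {
      "start": 1299,
      "end": 1324,
      "code": 3,
      "name": "IDR-3"
    },
    {
      "start": 1343,
      "end": 1405,
      "code": 4,
      "name": "IDR-4"
    }
  ],
  "comp_bias": [
    {
      "start": 175,
      "end": 205,
      "code": 1,
      "name": "comp_bias_1"
    },
    {
      "start": 560,
      "end": 585,
      "code": 2,
      "name": "comp_bias_2"
    },
    {
      "start": 700,
      "end": 730,
      "code": 3,
      "name": "comp_bias_3"
    },
    {
      "start": 1270,
      "end": 1295,
      "code": 4,
      "name": "comp_bias_4"
    },
    {
      "start": 1900,
      "end": 1930,
      "code": 5,
      "name": "comp_bias_5"
    }
  ],
  "coiled_coil": [
    {
      "start": 600,
      "end": 640,
      "code": 1,
      "name": "coiled_coil_1"
    }
  ],
  "exons": [
    {
      "start": 1,
      "end": 43,
      "code": 1,
      "name": "exon_01"
    },
    {
      "start": 44,
      "end": 86,
      "code": 2,
      "name": "exon_02"
    },
    {
      "start": 87,
      "end": 129,
      "code": 3,
      "name": "exon_03"
    },
    {
      "start": 130,
      "end": 172,
      "code": 4,
      "name": "exon_04"
    },
    {
      "start": 173,
      "end": 215,
      "code": 5,
      "name": "exon_05"
    },
    {
      "start": 216,
      "end": 258,
      "code": 6,
      "name": "exon_06"
    },
    {
      "start": 259,
      "end": 301,
      "code": 7,
      "name": "exon_07"
    },
    {
      "start": 302,
      "end": 344,
      "code": 8,
      "name": "exon_08"
    },
    {
      "start": 345,
      "end": 387,
      "code": 9,
      "name": "exon_09"
    },
    {
      "start": 388,
      "end": 430,
      "code": 10,
      "name": "exon_10"
    },
    {
      "start": 431,
      "end": 473,
      "code": 11,
      "name": "exon_11"
    },
    {
      "start": 474,
      "end": 516,
      "code": 12,
      "name": "exon_12"
    },
    {
      "start": 517,
      "end": 559,
      "code": 13,
      "name": "exon_13"
    },
    {
      "start": 560,
      "end": 602,
      "code": 14,
      "name": "exon_14"
    },
    {
      "start": 603,
      "end": 645,
      "code": 15,
      "name": "exon_15"
    },
    {
      "start": 646,
      "end": 688,
      "code": 16,
      "name": "exon_16"
    },
    {
      "start": 689,
      "end": 731,
      "code": 17,
      "name": "exon_17"
    },
    {
      "start": 732,
      "end": 774,
      "code": 18,
      "name": "exon_18"
    },
    {
      "start": 775,
      "end": 817,
      "code": 19,
      "name": "exon_19"
    },
    {
      "start": 818,
      "end": 860,
      "code": 20,
      "name": "exon_20"
    },
    {
      "start": 861,
      "end": 903,
      "code": 21,
      "name": "exon_21"
    },
    {
      "start": 904,
      "end": 946,
      "code": 22,
      "name": "exon_22"
    },
    {
      "start": 947,
      "end": 990,
      "code": 23,
      "name": "exon_23"
    },
    {
      "start": 991,
      "end": 1033,
      "code": 24,
      "name": "exon_24"
    },
    {
      "start": 1034,
      "end": 1076,
      "code": 25,
      "name": "exon_25"
    },
    {
      "start": 1077,
      "end": 1119,
      "code": 26,
      "name": "exon_26"
    },
    {
      "start": 1120,
      "end": 1162,
      "code": 27,
      "name": "exon_27"
    },
    {
      "start": 1163,
      "end": 1205,
      "code": 28,
      "name": "exon_28"
    },
    {
      "start": 1206,
      "end": 1248,
      "code": 29,
      "name": "exon_29"
    },
    {
      "start": 1249,
      "end": 1291,
      "code": 30,
      "name": "exon_30"
    },
    {
      "start": 1292,
      "end": 1334,
      "code": 31,
      "name": "exon_31"
    },
    {
      "start": 1335,
      "end": 1377,
      "code": 32,
      "name": "exon_32"
    },
    {
      "start": 1378,
      "end": 1420,
      "code": 33,
      "name": "exon_33"
    },
    {
      "start": 1421,
      "end": 1463,
      "code": 34,
      "name": "exon_34"
    },
    {
      "start": 1464,
      "end": 1506,
      "code": 35,
      "name": "exon_35"
    },
    {
      "start": 1507,
      "end": 1549,
      "code": 36,
      "name": "exon_36"
    },
    {
      "start": 1550,
      "end": 1592,
      "code": 37,
      "name": "exon_37"
    },
    {
      "start": 1593,
      "end": 1635,
      "code": 38,
      "name": "exon_38"
    },
    {
      "start": 1636,
      "end": 1678,
      "code": 39,
      "name": "exon_39"
    },
    {
      "start": 1679,
      "end": 1721,
      "code": 40,
      "name": "exon_40"
    },
    {
      "start": 1722,
      "end": 1764,
      "code": 41,
      "name": "exon_41"
    },
    {
      "start": 1765,
      "end": 1807,
      "code": 42,
      "name": "exon_42"
    },
    {
      "start": 1808,
      "end": 1850,
      "code": 43,
      "name": "exon_43"
    },
    {
      "start": 1851,
      "end": 1893,
      "code": 44,
      "name": "exon_44"
    },
    {
      "start": 1894,
      "end": 1936,
      "code": 45,
      "name": "exon_45"
    },
    {
      "start": 1937,
      "end": 1979,
      "code": 46,
      "name": "exon_46"
    }
  ]
}
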