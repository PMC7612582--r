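{
  "Model": {
    "Name": "FRC_metabolism",
    "Variables": [
      {
        "Id": 1,
        "Name": "Ext_Lactate",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": ""
      },
      {
        "Id": 2,
        "Name": "Ext_Protons",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": ""
      },
      {
        "Id": 3,
        "Name": "MCT1",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": ""
      },
      {
        "Id": 4,
        "Name": "Int_Lactate",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": ""
      },
      {
        "Id": 5,
        "Name": "H_in",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": ""
      },
      {
        "Id": 6,
        "Name": "Glycolysis",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": "4 - H_in"
      },
      {
        "Id": 7,
        "Name": "Pyruvate",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": "ceil(avg(Glycolysis, Int_Lactate))"
      },
      {
        "Id": 8,
        "Name": "AcetylCoA",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": ""
      },
      {
        "Id": 9,
        "Name": "TCA_flux",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": "min(AcetylCoA, 5 - H_in, 2)"
      },
      {
        "Id": 10,
        "Name": "Acetylcarnitine",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": "AcetylCoA - TCA_flux + 2"
      },
      {
        "Id": 11,
        "Name": "NADH",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": ""
      },
      {
        "Id": 12,
        "Name": "ETC",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": "min(NADH + Uncoupling, 5 - ProtonGradient + Uncoupling) * (1 - RotAA)"
      },
      {
        "Id": 13,
        "Name": "ProtonGradient",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": "2 * ETC + 2 - 2 * ATP_Synthase - 3 * Uncoupling"
      },
      {
        "Id": 14,
        "Name": "ATP_Synthase",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": "2 * (1 - Oligomycin)"
      },
      {
        "Id": 15,
        "Name": "Uncoupling",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": "4 * FCCP"
      },
      {
        "Id": 16,
        "Name": "ATP",
        "RangeFrom": 0,
        "RangeTo": 4,
        "Formula": ""
      },
      {
        "Id": 17,
        "Name": "OCR",
        "RangeFrom": 0,
        "RangeTo": 10,
        "Formula": "ceil(5 * ETC / 2)"
      },
      {
        "Id": 18,
        "Name": "Counter",
        "RangeFrom": 0,
        "RangeTo": 100,
        "Formula": "Counter + 1"
      },
      {
        "Id": 19,
        "Name": "Oligomycin",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": ""
      },
      {
        "Id": 20,
        "Name": "FCCP",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": ""
      },
      {
        "Id": 21,
        "Name": "RotAA",
        "RangeFrom": 0,
        "RangeTo": 1,
        "Formula": ""
      }
    ],
    "Relationships": [
      {
        "Id": 1,
        "FromVariable": 1,
        "ToVariable": 3,
        "Type": "Activator"
      },
      {
        "Id": 2,
        "FromVariable": 3,
        "ToVariable": 4,
        "Type": "Activator"
      },
      {
        "Id": 3,
        "FromVariable": 1,
        "ToVariable": 4,
        "Type": "Activator"
      },
      {
        "Id": 4,
        "FromVariable": 2,
        "ToVariable": 5,
        "Type": "Activator"
      },
      {
        "Id": 5,
        "FromVariable": 5,
        "ToVariable": 6,
        "Type": "Inhibitor"
      },
      {
        "Id": 6,
        "FromVariable": 6,
        "ToVariable": 7,
        "Type": "Activator"
      },
      {
        "Id": 7,
        "FromVariable": 4,
        "ToVariable": 7,
        "Type": "Activator"
      },
      {
        "Id": 8,
        "FromVariable": 7,
        "ToVariable": 8,
        "Type": "Activator"
      },
      {
        "Id": 9,
        "FromVariable": 8,
        "ToVariable": 9,
        "Type": "Activator"
      },
      {
        "Id": 10,
        "FromVariable": 5,
        "ToVariable": 9,
        "Type": "Inhibitor"
      },
      {
        "Id": 11,
        "FromVariable": 8,
        "ToVariable": 10,
        "Type": "Activator"
      },
      {
        "Id": 12,
        "FromVariable": 9,
        "ToVariable": 10,
        "Type": "Inhibitor"
      },
      {
        "Id": 13,
        "FromVariable": 9,
        "ToVariable": 11,
        "Type": "Activator"
      },
      {
        "Id": 14,
        "FromVariable": 11,
        "ToVariable": 12,
        "Type": "Activator"
      },
      {
        "Id": 15,
        "FromVariable": 13,
        "ToVariable": 12,
        "Type": "Inhibitor"
      },
      {
        "Id": 16,
        "FromVariable": 15,
        "ToVariable": 12,
        "Type": "Activator"
      },
      {
        "Id": 17,
        "FromVariable": 21,
        "ToVariable": 12,
        "Type": "Inhibitor"
      },
      {
        "Id": 18,
        "FromVariable": 12,
        "ToVariable": 13,
        "Type": "Activator"
      },
      {
        "Id": 19,
        "FromVariable": 14,
        "ToVariable": 13,
        "Type": "Inhibitor"
      },
      {
        "Id": 20,
        "FromVariable": 15,
        "ToVariable": 13,
        "Type": "Inhibitor"
      },
      {
        "Id": 21,
        "FromVariable": 19,
        "ToVariable": 14,
        "Type": "Inhibitor"
      },
      {
        "Id": 22,
        "FromVariable": 20,
        "ToVariable": 15,
        "Type": "Activator"
      },
      {
        "Id": 23,
        "FromVariable": 14,
        "ToVariable": 16,
        "Type": "Activator"
      },
      {
        "Id": 24,
        "FromVariable": 6,
        "ToVariable": 16,
        "Type": "Activator"
      },
      {
        "Id": 25,
        "FromVariable": 12,
        "ToVariable": 17,
        "Type": "Activator"
      },
      {
        "Id": 26,
        "FromVariable": 18,
        "ToVariable": 18,
        "Type": "Activator"
      }
    ]
  }
}
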