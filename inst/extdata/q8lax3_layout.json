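{
  "segment": "Q8LAx3",
  "featuresArray": [
    {
      "featureId": "UPKB_Q8LAX3_PEPTIDE_74_96",
      "featureStart": 74,
      "featureEnd": 96,
      "featureTypeLabel": "active_peptide",
      "typeCode": "SO:0001064",
      "typeCategory": "Molecule processing",
      "featureLabel": "Elicitor peptide 3",
      "evidenceText": "UniProt",
      "type": "rect",
      "fillOpacity": 0.5,
      "stroke": "#7DBAA4",
      "height": 10,
      "r": 10,
      "y": 56,
      "x": 529,
      "cy": 56,
      "cx": 529,
      "strokeWidth": 1,
      "fill": "#7DBAA4",
      "width": 151,
      "nonOverlappingStyle": { "heightOrRadius": 10, "y": 56 },
      "centeredStyle": { "heightOrRadius": 40, "y": 75 },
      "rowsStyle": { "heightOrRadius": 10, "y": 157 }
    }
  ],
  "legend": [],
  "configuration": {
    "style": "nonOverlapping",
    "requestedStart": 1,
    "requestedStop": 96,
    "rulerY": 20,
    "rulerLength": 660,
    "belowRuler": 30,
    "pixelsDivision": 50,
    "aboveRuler": 10,
    "sizeY": 76,
    "sizeX": 700,
    "rightMargin": 20,
    "leftMargin": 20,
    "sequenceLineY": 54,
    "sequenceLength": 96,
    "unitsize": 6.875,
    "verticalGrid": false,
    "horizontalGrid": false,
    "dasSources": "http://www.ebi.ac.uk/das-srv/uniprot/das/uniprot",
    "dasReference": "http://www.ebi.ac.uk/das-srv/uniprot/das/uniprot"
  }
}
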