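{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Resolved layout document",
  "description": "A complete drawing: every pixel coordinate is already computed, so renderers perform no layout math. featuresArray carries flat geometry for the active style plus per-style blocks; 'ruler' and 'sourceFeatures' are extensions of this package (ticks for renderers, original features so documents can be re-laid-out or zoomed). All pixel fields are integers except unitsize. dasSources/dasReference are optional pass-through strings.",
  "type": "object",
  "required": ["segment", "featuresArray", "legend", "configuration"],
  "properties": {
    "segment": { "type": "string" },
    "featuresArray": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["featureId", "featureStart", "featureEnd", "x", "y",
                     "width"],
        "properties": {
          "featureId": { "type": "string" },
          "featureStart": { "type": "integer" },
          "featureEnd": { "type": "integer" },
          "featureTypeLabel": { "type": "string" },
          "typeCode": { "type": "string" },
          "typeCategory": { "type": "string" },
          "featureLabel": { "type": "string" },
          "evidenceText": { "type": "string" },
          "evidenceCode": { "type": "string" },
          "type": {
            "enum": ["rect", "circle", "diamond", "triangle", "hexagon",
                     "wave", "bridge", "line"]
          },
          "fill": { "type": "string" },
          "stroke": { "type": "string" },
          "fillOpacity": { "type": "number" },
          "strokeWidth": { "type": "number" },
          "x": { "type": "integer" },
          "y": { "type": "integer" },
          "width": { "type": "integer", "minimum": 0 },
          "height": { "type": "number" },
          "cx": { "type": "integer" },
          "cy": { "type": "number" },
          "r": { "type": "number" },
          "trackIndex": { "type": "integer", "minimum": 0 },
          "clippedLeft": { "type": "boolean" },
          "clippedRight": { "type": "boolean" },
          "tooltip": { "type": "string" },
          "nonOverlappingStyle": { "$ref": "#/definitions/styleBlock" },
          "centeredStyle": { "$ref": "#/definitions/styleBlock" },
          "rowsStyle": { "$ref": "#/definitions/styleBlock" }
        }
      }
    },
    "legend": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "typeLabel": { "type": "string" },
          "typeCategory": { "type": "string" },
          "color": { "type": "string" },
          "glyph": { "type": "string" }
        }
      }
    },
    "configuration": {
      "type": "object",
      "required": ["style", "sizeX", "leftMargin", "rightMargin",
                   "requestedStart", "requestedStop", "sequenceLength",
                   "unitsize", "rulerLength"],
      "properties": {
        "style": { "enum": ["nonOverlapping", "rows", "centered"] },
        "sizeX": { "type": "number" },
        "sizeY": { "type": "number" },
        "leftMargin": { "type": "number" },
        "rightMargin": { "type": "number" },
        "requestedStart": { "type": "integer", "minimum": 1 },
        "requestedStop": { "type": "integer", "minimum": 1 },
        "sequenceLength": { "type": "integer", "minimum": 1 },
        "pixelsDivision": { "type": "number", "exclusiveMinimum": 0 },
        "rulerY": { "type": "number" },
        "aboveRuler": { "type": "number" },
        "belowRuler": { "type": "number" },
        "sequenceLineY": { "type": "number" },
        "heightOrRadius": { "type": "number", "exclusiveMinimum": 0 },
        "trackGap": { "type": "number" },
        "rulerLength": { "type": "number" },
        "unitsize": { "type": "number", "exclusiveMinimum": 0 },
        "verticalGrid": { "type": "boolean" },
        "horizontalGrid": { "type": "boolean" },
        "dasSources": { "type": "string" },
        "dasReference": { "type": "string" }
      }
    },
    "ruler": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["x"],
        "properties": {
          "x": { "type": "integer" },
          "label": { "type": ["integer", "null"] }
        }
      }
    },
    "sourceFeatures": {
      "type": "array",
      "items": { "type": "object" }
    }
  },
  "definitions": {
    "styleBlock": {
      "type": "object",
      "properties": {
        "heightOrRadius": { "type": "number" },
        "y": { "type": "integer" }
      }
    }
  }
}
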