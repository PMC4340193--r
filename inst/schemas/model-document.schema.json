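{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://ns.owlgen.org/schemas/model-document",
  "title": "owlgen model-description document",
  "type": "object",
  "required": ["classes"],
  "additionalProperties": false,
  "properties": {
    "classes": {
      "type": "array",
      "items": { "$ref": "#/$defs/class" }
    }
  },
  "$defs": {
    "class": {
      "type": "object",
      "required": ["name"],
      "additionalProperties": false,
      "properties": {
        "name": { "type": "string", "pattern": "^[A-Za-z_][A-Za-z0-9_]*$" },
        "package": { "type": "string" },
        "extends": { "type": "string" },
        "enum": { "type": "array", "items": { "type": "string" }, "minItems": 1 },
        "fields": { "type": "array", "items": { "$ref": "#/$defs/field" } },
        "annotations": { "type": "array", "items": { "$ref": "#/$defs/annotation" } }
      }
    },
    "field": {
      "type": "object",
      "required": ["name", "type"],
      "additionalProperties": false,
      "properties": {
        "name": { "type": "string", "pattern": "^[A-Za-z_][A-Za-z0-9_]*$" },
        "type": {
          "type": "string",
          "description": "an atomic kind (string|integer|decimal|boolean|date|datetime) or the simple name of another class in the model"
        },
        "collection": { "type": "boolean", "default": false },
        "id": { "type": "boolean", "default": false },
        "annotations": { "type": "array", "items": { "$ref": "#/$defs/annotation" } }
      }
    },
    "annotation": {
      "type": "object",
      "required": ["marker"],
      "additionalProperties": false,
      "properties": {
        "marker": {
          "enum": ["EquivalentClass", "EquivalentProperty", "Symmetric",
                   "Inverse", "AllValuesFrom", "Transitive", "AllDifferent",
                   "DifferentFrom", "SameAs", "Cardinality", "MaxCardinality",
                   "MinCardinality", "SomeValuesFrom"]
        },
        "resource": { "type": "string", "format": "iri" },
        "number": { "type": "integer", "minimum": 0 },
        "string_values": { "type": "array", "items": { "type": "string" }, "minItems": 1 }
      }
    }
  }
}
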