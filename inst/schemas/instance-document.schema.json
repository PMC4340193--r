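{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://ns.owlgen.org/schemas/instance-document",
  "title": "owlgen instance document",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["class", "id"],
    "additionalProperties": false,
    "properties": {
      "class": { "type": "string" },
      "id": { "type": ["string", "integer"] },
      "values": {
        "type": "object",
        "description": "field name -> atomic value, referenced instance id, enumeration literal, or an array of ids for collections",
        "additionalProperties": {
          "type": ["string", "number", "boolean", "array"],
          "items": { "type": ["string", "number"] }
        }
      }
    }
  }
}
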