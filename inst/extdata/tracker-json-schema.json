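{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tracker-json lineage dialect",
  "description": "Single-object export of tracked nuclei: per-track point lists plus division links. Unknown additional keys are ignored by the reader.",
  "type": "object",
  "required": ["tracks"],
  "properties": {
    "tracks": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "points"],
        "properties": {
          "id": {"type": ["string", "integer"]},
          "points": {
            "type": "array",
            "description": "one [frame, x_um, y_um, z_um] quadruple per frame, frames consecutive",
            "items": {
              "type": "array",
              "minItems": 4,
              "maxItems": 4,
              "items": {"type": "number"}
            }
          }
        }
      }
    },
    "links": {
      "type": "array",
      "description": "[child_id, parent_id] pairs; each parent appears exactly twice",
      "items": {
        "type": "array",
        "minItems": 2,
        "maxItems": 2
      }
    },
    "movie_end_frame": {"type": "integer"},
    "frame_interval_h": {"type": "number"},
    "end_reasons": {
      "type": "object",
      "description": "track_id -> 'death' or 'lost' for tracks ending early",
      "additionalProperties": {"enum": ["death", "lost"]}
    }
  }
}
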