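{
  "report_id": "25319",
  "sex": "F",
  "structured_dates": {
    "vaccinated": "1990-03-29",
    "onset": "1990-03-29"
  },
  "vaccines": ["ENGERIX-B"],
  "symptoms": ["Influenza"],
  "narrative_annotations": [
    {
      "span": "1ST ENGERIX-B DOSE",
      "kind": "event",
      "attributes": {"id": "dose1"}
    },
    {
      "span": "3-29-90",
      "kind": "time",
      "attributes": {"event": "dose1"}
    },
    {
      "span": "FLU-LIKE SYMPTOMS",
      "kind": "event",
      "attributes": {"id": "e2"}
    },
    {
      "span": "after",
      "kind": "relation",
      "attributes": {"source": "e2", "relation": "after", "target": "dose1"}
    }
  ]
}
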