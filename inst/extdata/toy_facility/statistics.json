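{
  "id": "toy-hc-01",
  "level": "3",
  "trustee": "public",
  "location": "rural",
  "province": "Central",
  "beds": 12,
  "outpatient_visits": 5000,
  "admissions": 600,
  "bed_days": 3600,
  "catchment_population": 25000
}
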