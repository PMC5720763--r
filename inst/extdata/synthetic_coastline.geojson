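{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": {"name": "synthetic mainland"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[
          [-6.2, 53.9], [-5.6, 53.95], [-5.3, 54.3], [-6.4, 54.4],
          [-6.2, 53.9]
        ]]
      }
    },
    {
      "type": "Feature",
      "properties": {"name": "synthetic island"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[
          [-5.4, 53.3], [-5.2, 53.3], [-5.2, 53.5], [-5.4, 53.5],
          [-5.4, 53.3]
        ]]
      }
    },
    {
      "type": "Feature",
      "properties": {"name": "synthetic skerries"},
      "geometry": {
        "type": "MultiPolygon",
        "coordinates": [
          [[[-6.1, 53.1], [-6.0, 53.1], [-6.0, 53.2], [-6.1, 53.2],
            [-6.1, 53.1]]],
          [[[-5.0, 53.0], [-4.9, 53.0], [-4.9, 53.1], [-5.0, 53.1],
            [-5.0, 53.0]]]
        ]
      }
    }
  ]
}
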