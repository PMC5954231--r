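# synthetic dressing-session event log: shirt then pants, continuous mode,
# one wrong drawer, one acted error, one stress episode
{"t": 0.0, "kind": "presence"}
{"t": 2.0, "kind": "drawer_open", "index": 2}
{"t": 4.0, "kind": "drawer_open", "index": 1}
{"t": 6.0, "kind": "rfid_removed", "drawer": 1}
{"t": 10.0, "kind": "detection", "label": "B", "garment": "shirt"}
{"t": 15.0, "kind": "detection", "label": "R", "garment": "shirt"}
{"t": 16.0, "kind": "stress", "level": 0.6}
{"t": 17.0, "kind": "stress", "level": 0.9}
{"t": 18.0, "kind": "stress", "level": 0.3}
{"t": 20.0, "kind": "detection", "label": "L", "garment": "shirt"}
{"t": 20.5, "kind": "detection", "label": "A", "garment": "shirt"}
{"t": 25.0, "kind": "detection", "label": "C", "garment": "shirt"}
{"t": 27.0, "kind": "drawer_close", "index": 1}
{"t": 29.0, "kind": "drawer_open", "index": 2}
{"t": 31.0, "kind": "rfid_removed", "drawer": 2}
{"t": 35.0, "kind": "detection", "label": "R", "garment": "pants"}
{"t": 40.0, "kind": "detection", "label": "L", "garment": "pants"}
{"t": 45.0, "kind": "detection", "label": "C", "garment": "pants"}
{"t": 47.0, "kind": "drawer_close", "index": 2}
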