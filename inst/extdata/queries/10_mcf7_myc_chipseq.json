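{
  "gcm": {
    "source": ["encode"],
    "assembly": ["hg19"],
    "technique": ["chip-seq"],
    "file_format": ["narrowpeak"],
    "cell": ["mcf-7"],
    "target": ["myc"]
  },
  "type": "original",
  "kv": {}
}
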