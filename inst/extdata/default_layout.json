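{
  "segments": [
    {
      "role": "barcodeB",
      "length": 8
    },
    {
      "role": "linker2",
      "length": 30
    },
    {
      "role": "barcodeA",
      "length": 8
    },
    {
      "role": "linker1",
      "length": 30
    },
    {
      "role": "genomic",
      "length": null
    }
  ],
  "linker1": "CGGCTCTCCTAGTTAAGTGAAGCTATCTTA",
  "linker2": "GAGACACTGAAAGTCTCCTCGTCAGCACTC"
}
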