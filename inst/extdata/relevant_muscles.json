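{
  "A": ["OOP", "OOM", "BUC"],
  "B": ["LLSAN"],
  "C": ["DAO", "MEN"],
  "D": ["LLSAN", "RIS", "ZYG", "LAO", "DAO", "DLI"],
  "E": ["OOP", "OOM", "LLSAN", "RIS", "ZYG", "LAO", "BUC"],
  "F": ["OOP", "OOM", "LLSAN", "RIS", "ZYG", "LAO", "BUC"]
}
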