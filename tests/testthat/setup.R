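# warm the GFF3 import machinery once so per-test timings reflect the
# operations themselves, not one-off lazy loading of the import stack
local({
  d <- tempfile()
  writeLines(c("##gff-version 3",
               "chrW\tw\tgene\t1\t10\t.\t+\t.\tID=W1"), d)
  invisible(rtracklayer::import(d, format = "gff3"))
})
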