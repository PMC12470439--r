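# Convert a small-RNA simulation truth table into strand-separated hit
# frames on genome coordinates (used to feed pingpong()).
truth_hits <- function(truth) {
  tt <- truth[truth$category != "background", , drop = FALSE]
  s <- tt[tt$strand == "+", , drop = FALSE]
  a <- tt[tt$strand == "-", , drop = FALSE]
  list(sense = data.frame(start = s$start, read_len = s$end - s$start),
       antisense = data.frame(start = a$start, read_len = a$end - a$start))
}
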