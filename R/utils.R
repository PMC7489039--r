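# bind a list of single-row data frames, falling back to a prototype when empty
rbind_rows <- function(rows, empty) {
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
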