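# Shared nucleotide constants (needed at load time by several files).

DNA_STATES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", V = "B", D = "H", H = "D", U = "A", "?" = "?")

revcomp <- function(s) {
  x <- rev(strsplit(toupper(s), "")[[1]])
  paste(unname(COMPLEMENT[x]), collapse = "")
}
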