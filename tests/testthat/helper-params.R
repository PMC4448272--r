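# shared fixtures: one parameter set for the whole suite
PARAMS <- nn_params()

# RT in kcal/mol recomputed from first principles, independent of the package
RT_KCAL <- 8.3144621 * 310.15 / 4184

enc <- function(x) premirscan:::.encode_seq(premirscan::rna_normalize(x))

# random arm pair of given length; when complement = TRUE st2 pairs st1
random_arm_pair <- function(l, complement = FALSE) {
  bases <- c("A", "C", "G", "U")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  st1 <- sample(bases, l, replace = TRUE)
  st2 <- if (complement) unname(comp[st1]) else sample(bases, l, replace = TRUE)
  list(st1 = paste(st1, collapse = ""), st2 = paste(st2, collapse = ""))
}
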