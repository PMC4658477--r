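# shared fixtures, all built in code at test time

# Table 2 cancer gene-set cardinalities and the background gene count
cancer_sizes <- c(BVG = 125, CCG = 522, ELG = 107, GGG = 260,
                  LDG = 137, NBG = 435, NRG = 114)
cancer_n <- 20687

write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

tiny_collection <- function() {
  set_collection(list(A = c("a", "b", "c"),
                      B = c("b", "c", "d"),
                      C = c("c", "d", "e")),
                 background = 10)
}

# a deterministic 7-set collection over a synthetic background
seven_set_collection <- function(n = 2000, seed = 7) {
  make_fixture_collection(n, sizes = c(60, 80, 100, 120, 140, 50, 70),
                          seed = seed)
}
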