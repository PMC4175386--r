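# Shared fixtures, built in code at test time.

# small certified-separable 3-blob dataset used across modules
blob3 <- function(seed = 2) synth_blobs(n_classes = 3, n_per_class = 15,
                                        dim = 2, separation = 4, sd = 0.3,
                                        seed = seed)

# two-class Gaussian pair at means +/-(2,2), sd 0.3 (binary-SVM fixture)
gauss_pair <- function(n_per_class = 20, seed = 1) {
  d <- synth_blobs(n_classes = 2, n_per_class = n_per_class, dim = 2,
                   separation = 2 * sqrt(2), sd = 0.3, seed = seed)
  list(x = d$table$values, y = ifelse(d$labels$labels == 1, 1, -1))
}

# write a small delimited file and return its path
write_tmp_data <- function(lines) {
  tf <- tempfile(fileext = ".data")
  writeLines(lines, tf)
  tf
}

linear_cfg <- function(C = 1) svm_config(kernel_spec("linear"), C = C)
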