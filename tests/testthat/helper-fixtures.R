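# small in-code fixtures shared across test files

toy_expression <- function() {
  expression_matrix(
    rbind(gA = c(1.0, 2.0, 5.0, 6.0),
          gB = c(3.0, 3.5, 3.2, 3.8),
          gC = c(2.0, 1.0, 1.5, 2.5)),
    group_labels = c("ctl", "ctl", "trt", "trt"))
}

write_toy_tsv <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("toy")
    dir.create(dir)
  }
  em <- toy_expression()
  mat_path <- file.path(dir, "expr.tsv")
  lab_path <- file.path(dir, "labels.tsv")
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  colnames(df) <- c("gene_id", paste0("s", 1:4))
  write.table(df, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(paste0("s", 1:4),
                   c("ctl", "ctl", "trt", "trt"), sep = "\t"), lab_path)
  list(matrix = mat_path, labels = lab_path, dir = dir)
}
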