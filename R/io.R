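#' Write / read a gene-by-sample count matrix with its sample sheet
#'
#' Counts go to a TSV (gene id column + one column per sample); the sample
#' sheet (sample, group) to `<path>.samples.csv`.
#'
#' @param counts genes x samples matrix.
#' @param samples data.frame with columns `sample`, `group`.
#' @param path TSV path.
#' @export
write_counts <- function(counts, samples, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(samples, paste0(path, ".samples.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene
  samples <- read.csv(paste0(path, ".samples.csv"))
  list(counts = counts, samples = samples)
}

#' Write / read a long-format qPCR Ct table
#'
#' @param ct data.frame with columns `sample`, `group`, `gene`, `ct`.
#' @param path CSV path.
#' @export
write_ct_table <- function(ct, path) {
  write.csv(ct[, c("sample", "group", "gene", "ct")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) read.csv(path)

#' Published-style summary table of cystometric and voiding-spot variables
#'
#' Loads the packaged summary-statistics tables (per-group mean, SD, n for
#' each variable and experiment), the input format of the
#' summary-statistics tests ([welch_t_from_summary()], [anova_dunnett()],
#' ...).
#'
#' @param which `"cystometry"` or `"vsa"`.
#' @return data.frame: experiment, group, variable, mean, sd, n.
#' @export
load_summary_table <- function(which = c("cystometry", "vsa")) {
  which <- match.arg(which)
  f <- system.file("extdata", sprintf("%s_group_summaries.csv", which),
                   package = "uroquant", mustWork = TRUE)
  read.csv(f)
}
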