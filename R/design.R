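#' Construct a paired study design
#'
#' Builds the library table for a paired two-condition design in which every
#' donor contributes replicate libraries to both conditions. The default
#' reproduces the study layout this package emulates: 6 donors x
#' \{white, beige\} x 3 replicates = 36 libraries.
#'
#' @param n_donors Number of donors (paired across conditions).
#' @param conditions Character vector of the two condition labels; the second
#'   is treated as the "treatment" level throughout (effects are reported as
#'   second minus first, i.e. beige minus white by default).
#' @param n_replicates Replicates per donor and condition.
#' @return A data.frame of class `study_design` with columns `library_id`,
#'   `donor`, `condition`, `replicate`.
#' @examples
#' d <- make_study_design()
#' nrow(d) # 36
#' @export
make_study_design <- function(n_donors = 6,
                              conditions = c("white", "beige"),
                              n_replicates = 3) {
  stopifnot(n_donors >= 1, n_replicates >= 1, length(conditions) == 2)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      condition = conditions,
                      donor = seq_len(n_donors),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("donor", "condition", "replicate")]
  grid$library_id <- sprintf("D%d_%s_R%d", grid$donor, grid$condition,
                             grid$replicate)
  design <- grid[, c("library_id", "donor", "condition", "replicate")]
  design$donor <- factor(design$donor)
  design$condition <- factor(design$condition, levels = conditions)
  class(design) <- c("study_design", "data.frame")
  design
}

#' Read or write a design file
#'
#' Plain TSV with header `library_id donor condition replicate`.
#'
#' @param path File path.
#' @param design A `study_design` data.frame (for writing).
#' @return `read_design` returns a `study_design` data.frame.
#' @export
read_design <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("library_id", "donor", "condition", "replicate")
  if (!all(need %in% names(d)))
    stop("design file must have columns: ", paste(need, collapse = ", "))
  d$donor <- factor(d$donor)
  d$condition <- factor(d$condition, levels = unique(d$condition))
  class(d) <- c("study_design", "data.frame")
  d
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Two-column condition indicator (0/1 for the second condition level).
condition_indicator <- function(design) {
  as.integer(design$condition == levels(design$condition)[2])
}
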