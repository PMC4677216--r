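# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

## Locale-independent lexicographic order, used wherever a deterministic
## tie-break on feature names is required.
lex_order <- function(x) order(x, method = "radix")

stop_balcornet <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "balcornet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_that <- function(ok, msg, class = "balcornet_input_error") {
  if (!isTRUE(ok)) stop_balcornet(msg, class)
  invisible(TRUE)
}

## TSV writer used by every stage. `comments` are emitted as '# ' header lines
## so downstream tools can skip them with comment.char = "#".
write_tsv <- function(x, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

## Group labels used throughout. "sarcoidosis" is the pooled patient group
## (regressing + progressing) and is derived, never stored in metadata.
GROUP_LEVELS <- c("control", "regressing", "progressing")

group_samples <- function(meta, group) {
  if (is.null(group) || identical(group, "all")) return(meta$sample_id)
  if (identical(group, "sarcoidosis")) {
    return(meta$sample_id[meta$group %in% c("regressing", "progressing")])
  }
  assert_that(group %in% GROUP_LEVELS,
              sprintf("unknown group '%s'", group))
  meta$sample_id[meta$group == group]
}

check_expr_meta <- function(expr, meta) {
  assert_that(is.matrix(expr) && is.numeric(expr),
              "expression must be a numeric samples x features matrix")
  assert_that(!is.null(rownames(expr)) && !is.null(colnames(expr)),
              "expression matrix must carry sample and feature names")
  assert_that(all(c("sample_id", "group") %in% names(meta)),
              "metadata must have columns sample_id and group")
  assert_that(!anyDuplicated(meta$sample_id),
              "duplicated sample_id in metadata")
  assert_that(setequal(rownames(expr), meta$sample_id) &&
                nrow(expr) == nrow(meta),
              "expression samples and metadata samples do not match",
              class = "balcornet_sample_mismatch")
  invisible(TRUE)
}
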