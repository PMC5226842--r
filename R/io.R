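#' Read a binary response matrix from CSV
#'
#' Expects a header row of item labels, one row per person, cells in
#' \{0, 1\}; an optional first column `person_id` supplies row labels.
#'
#' @param path CSV file.
#' @return integer matrix (persons x items) with `person_id` row names
#'   when present.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- NULL
  if (tolower(names(df)[1]) == "person_id") {
    ids <- as.character(df[[1]])
    df <- df[-1]
  }
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("responses must be 0/1")
  rownames(m) <- ids
  m
}

#' Write a binary response matrix to CSV
#'
#' @param responses 0/1 matrix (persons x items); row names, if any, are
#'   written as a `person_id` column.
#' @param path output CSV file.
#' @export
write_responses <- function(responses, path) {
  df <- as.data.frame(responses)
  if (is.null(names(df)) || all(grepl("^V[0-9]+$", names(df))))
    names(df) <- paste0("item", seq_len(ncol(df)))
  if (!is.null(rownames(responses)))
    df <- cbind(person_id = rownames(responses), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; comma-separated values are returned
#' as vectors, numeric where possible. Blank lines and `#` comments are
#' ignored.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    vals <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(
      replace(vals, vals %in% c("Inf", "inf"), "Inf")))
    out[[key]] <- if (all(!is.na(num))) num else vals
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param config named list; vector values are joined with commas.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write chain draws to CSV
#'
#' One row per (iteration, person) with columns `iteration`, `person_id`,
#' `theta`, `accepted`.
#'
#' @param fit an `sve_fit`.
#' @param path output CSV file.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "sve_fit"))
  n <- ncol(fit$draws)
  df <- data.frame(
    iteration = rep(seq_len(nrow(fit$draws)), times = n),
    person_id = rep(seq_len(n), each = nrow(fit$draws)),
    theta = as.numeric(fit$draws),
    accepted = as.integer(fit$accept))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
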