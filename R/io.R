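#' Read and write population tables as CSV
#'
#' The on-disk schema has header `s,age,parity,education,a,y`: `s`, `a`,
#' `y` binary (empty field for missing `a`/`y`), `age` in years, `parity`
#' coded `0`/`1`/`2` (2 meaning "2 or more"), `education` coded
#' `high`/`medium`/`low`. Rows with unparseable fields are rejected with
#' their line numbers; complete-case filtering is deferred to the
#' estimation functions.
#'
#' @param path File path.
#' @return `read_population_csv()` returns a population tibble;
#'   `write_population_csv()` returns `path` invisibly.
#' @export
read_population_csv <- function(path) {
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      s = readr::col_integer(), age = readr::col_double(),
      parity = readr::col_character(), education = readr::col_character(),
      a = readr::col_integer(), y = readr::col_integer()
    ),
    na = c("", "NA")
  ))
  required <- c("s", "age", "parity", "education", "a", "y")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("missing column(s) in %s: %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  problems <- readr::problems(raw)
  if (nrow(problems)) {
    abort(sprintf("unparseable field(s) in %s at line(s) %s",
                  path, paste(unique(problems$row + 1L), collapse = ", ")))
  }
  check_coded <- function(x, valid, name) {
    bad <- which(!is.na(x) & !(x %in% valid))
    if (length(bad)) {
      abort(sprintf("invalid %s value '%s' at line %d of %s",
                    name, x[bad[1]], bad[1] + 1L, path))
    }
  }
  check_coded(raw$parity, c("0", "1", "2"), "parity")
  check_coded(raw$education, .education_levels, "education")
  check_coded(raw$s, c(0L, 1L), "s")
  check_coded(raw$a, c(0L, 1L), "a")
  check_coded(raw$y, c(0L, 1L), "y")
  parity <- raw$parity
  parity[parity == "2"] <- "2+"
  tibble(
    s = raw$s, age = raw$age,
    parity = factor(parity, levels = .parity_levels),
    education = factor(raw$education, levels = .education_levels),
    a = raw$a, y = raw$y
  )
}

#' @rdname read_population_csv
#' @param pop Population tibble (columns among `s`, `age`, `parity`,
#'   `education`, `a`, `y`; absent ones are written as missing).
#' @export
write_population_csv <- function(pop, path) {
  pop <- check_covariates(pop)
  parity <- as.character(pop$parity)
  parity[parity == "2+"] <- "2"
  out <- tibble(
    s = if (is.null(pop[["s"]])) NA_integer_ else as.integer(pop$s),
    age = pop$age,
    parity = parity,
    education = as.character(pop$education),
    a = if (is.null(pop[["a"]])) NA_integer_ else as.integer(pop$a),
    y = if (is.null(pop[["y"]])) NA_integer_ else as.integer(pop$y)
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}
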