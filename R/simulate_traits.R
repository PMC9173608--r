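#' Simulate a mixed-type species trait table
#'
#' Emulates reef-fish ecological trait data: numeric traits (uniform on
#' the unit interval), unordered categorical traits with 2-6 levels, and ordinal
#' traits with ordered integer levels 1-5. The default layout (3 numeric,
#' 3 categorical, 2 ordinal) gives the 8 ecological traits used for
#' functional distinctiveness; tables are complete unless `na_rate > 0`.
#'
#' @param n_species number of species rows.
#' @param n_numeric,n_categorical,n_ordinal trait counts per type
#'   (at least one trait in total).
#' @param na_rate proportion of cells set missing at random (default 0).
#' @param seed integer seed.
#' @return A `data.frame` with a `species` column and one column per
#'   trait, plus attribute `trait_types` (named character vector with
#'   values `"numeric"`, `"categorical"`, `"ordinal"`).
#' @export
simulate_trait_table <- function(n_species, n_numeric = 3, n_categorical = 3,
                                 n_ordinal = 2, na_rate = 0, seed = 1L) {
  if (n_species < 1) stop_input("`n_species` must be >= 1")
  if (n_numeric + n_categorical + n_ordinal < 1)
    stop_input("need at least one trait column")
  if (na_rate < 0 || na_rate >= 1) stop_input("`na_rate` must be in [0, 1)")
  with_seed(seed, {
    out <- data.frame(species = sprintf("sp%03d", seq_len(n_species)),
                      stringsAsFactors = FALSE)
    types <- character(0)
    for (i in seq_len(n_numeric)) {
      nm <- paste0("num", i)
      out[[nm]] <- round(stats::runif(n_species), 6)
      types[nm] <- "numeric"
    }
    for (i in seq_len(n_categorical)) {
      nm <- paste0("cat", i)
      k <- sample(2:6, 1)
      out[[nm]] <- factor(sample(LETTERS[seq_len(k)], n_species,
                                 replace = TRUE))
      types[nm] <- "categorical"
    }
    for (i in seq_len(n_ordinal)) {
      nm <- paste0("ord", i)
      out[[nm]] <- factor(sample(1:5, n_species, replace = TRUE),
                          levels = 1:5, ordered = TRUE)
      types[nm] <- "ordinal"
    }
    if (na_rate > 0) {
      for (nm in names(types)) {
        hit <- stats::runif(n_species) < na_rate
        out[[nm]][hit] <- NA
      }
    }
    attr(out, "trait_types") <- types
    out
  })
}

#' Read / write a trait table with a column-type header
#'
#' The CSV carries a second line `# types: <type,type,...>` naming the
#' type of each trait column so mixed-type tables round-trip exactly.
#'
#' @param traits a trait table from [simulate_trait_table()] (or any
#'   data.frame with a `trait_types` attribute).
#' @param path CSV file path.
#' @export
write_trait_table <- function(traits, path) {
  types <- attr(traits, "trait_types")
  if (is.null(types)) stop_input("traits must carry a `trait_types` attribute")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(traits), collapse = ","), con)
  writeLines(paste0("# types: ",
                    paste(types[names(traits)[-1]], collapse = ",")), con)
  for (i in seq_len(nrow(traits))) {
    row <- vapply(traits[i, ], function(v)
      if (is.na(v)) "" else as.character(v), character(1))
    writeLines(paste(row, collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], ",")[[1]]
  types <- strsplit(sub("^# types: ", "", lines[2]), ",")[[1]]
  names(types) <- header[-1]
  body <- utils::read.csv(text = lines[-2], stringsAsFactors = FALSE,
                          na.strings = "")
  for (nm in names(types)) {
    body[[nm]] <- switch(types[[nm]],
      numeric = as.numeric(body[[nm]]),
      categorical = factor(body[[nm]]),
      ordinal = factor(body[[nm]], levels = sort(unique(
        stats::na.omit(body[[nm]]))), ordered = TRUE))
  }
  attr(body, "trait_types") <- types
  body
}
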