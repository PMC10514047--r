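# Interaction-energy tables: xvg-style two-column text (time [ps], energy
# [kJ/mol]); comment lines starting with '#' or '@' are ignored.

.energy_labels <- c("PP-intra", "PP-inter", "PP", "PW", "WW")

#' Create an interaction-energy series
#'
#' @param label component pair: one of `"PP-intra"`, `"PP-inter"`, `"PP"`
#'   (intra + inter), `"PW"`, `"WW"`.
#' @param time time axis (ps).
#' @param values energies (kJ/mol).
#' @return A `ct_energy_series`.
#' @export
energy_series <- function(label, time, values) {
  .assert(label %in% .energy_labels,
          paste0("label must be one of: ", paste(.energy_labels, collapse = ", ")))
  .assert(length(time) == length(values) && length(values) >= 1L,
          "time and values must be equal-length, non-empty")
  .assert(all(is.finite(values)), "energy values must be finite")
  o <- order(time)
  structure(list(label = label, time = time[o], values = values[o]),
            class = "ct_energy_series")
}

#' @export
print.ct_energy_series <- function(x, ...) {
  cat("<ct_energy_series> ", x$label, ": ", length(x$values),
      " samples, mean ", signif(mean(x$values), 6), " kJ/mol (SD ",
      signif(sd(x$values), 4), ")\n", sep = "")
  invisible(x)
}

#' @export
mean.ct_energy_series <- function(x, ...) mean(x$values)

#' Read an interaction-energy table
#'
#' @param path xvg-like two-column text file (time, energy).
#' @param label component-pair label, see [energy_series()].
#' @return A `ct_energy_series` with time-ordered samples.
#' @export
read_energy_table <- function(path, label) {
  .assert(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  .assert(length(idx) >= 1L, paste0("no data rows in ", path))
  t <- numeric(length(idx)); v <- numeric(length(idx))
  for (i in seq_along(idx)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[idx[i]]), "\\s+")[[1]]))
    if (length(f) < 2L || !all(is.finite(f[1:2])))
      stop("non-numeric data row at line ", idx[i], " of ", path, call. = FALSE)
    t[i] <- f[1]; v[i] <- f[2]
  }
  energy_series(label, t, v)
}

#' Write an interaction-energy table
#'
#' @param path output path.
#' @param es a [energy_series()].
#' @export
write_energy_table <- function(path, es) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("# condensotherm energy table: ", es$label),
               "@    xaxis label \"Time (ps)\"",
               "@    yaxis label \"Energy (kJ/mol)\""), con)
  writeLines(sprintf("%12.4f %16.6f", es$time, es$values), con)
  invisible(path)
}
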