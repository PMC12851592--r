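#' Countercurrent phototaxis assay record
#'
#' Per-tube fly counts from a three-trial countercurrent run. Tubes are
#' indexed by the number of times a fly approached the light (0..3); the
#' reported quantity of the assay is the fraction reaching tube 3, i.e.
#' responding on all three consecutive opportunities.
#'
#' @param assay_id Assay identifier.
#' @param genotype Genotype label.
#' @param sex `"male"`, `"female"` or `"mixed"`.
#' @param tube_counts Integer vector of length 4 (tubes 0..3), all >= 0,
#'   summing to at least 1.
#' @return An object of class `"phototaxis_assay"` with an `n_total` field.
#' @examples
#' a <- phototaxis_assay("a1", "control", "female", c(10, 5, 5, 20))
#' score_assay(a)  # 0.5
#' @export
phototaxis_assay <- function(assay_id, genotype, sex, tube_counts) {
  tc <- as.integer(tube_counts)
  if (length(tc) != 4L || any(is.na(tc)) || any(tc < 0)) {
    stop("tube_counts must be 4 non-negative integers (tubes 0..3)", call. = FALSE)
  }
  structure(list(assay_id = as.character(assay_id),
                 genotype = as.character(genotype), sex = as.character(sex),
                 tube_counts = tc, n_total = sum(tc)),
            class = "phototaxis_assay")
}

#' @export
print.phototaxis_assay <- function(x, ...) {
  cat(sprintf("phototaxis assay %s (%s, %s): tubes 0..3 = %s, n = %d\n",
              x$assay_id, x$genotype, x$sex,
              paste(x$tube_counts, collapse = "/"), x$n_total))
  invisible(x)
}

#' Score a phototaxis assay by its final-tube fraction
#'
#' @param assay A [phototaxis_assay()] with at least one fly.
#' @return The fraction of flies in the last tube (responded to light on all
#'   three trials), in `[0, 1]`.
#' @export
score_assay <- function(assay) {
  stopifnot(inherits(assay, "phototaxis_assay"))
  if (assay$n_total < 1L) stop("assay has no flies", call. = FALSE)
  if (sum(assay$tube_counts) != assay$n_total) {
    stop("tube counts do not sum to n_total", call. = FALSE)
  }
  assay$tube_counts[4] / assay$n_total
}

#' Expected final-tube fraction under independent trials
#'
#' If each fly passes each of the three trials independently with
#' probability `p_trial`, the expected fraction reaching the final tube is
#' `p_trial^3`.
#'
#' @param p_trial Per-trial success probability in `[0, 1]`.
#' @return `p_trial^3`.
#' @examples
#' expected_final_fraction(0.794)  # ~0.50
#' @export
expected_final_fraction <- function(p_trial) {
  if (!is.numeric(p_trial) || any(p_trial < 0) || any(p_trial > 1)) {
    stop("p_trial must be in [0, 1]", call. = FALSE)
  }
  p_trial^3
}

#' Summarize phototaxis scores by group
#'
#' Groups assays by genotype and/or sex and reports the mean, SD and count
#' of the scored final-tube fractions — the inputs to any downstream group
#' comparison. Groups with a single assay report `NA` SD; empty groups do
#' not occur (groups are formed from the assays present).
#'
#' @param assays A list of [phototaxis_assay()] objects.
#' @param group_keys Character vector of grouping fields, a subset of
#'   `c("genotype", "sex")`.
#' @return A data frame with the group key columns, `mean_fraction`, `sd`,
#'   `n_assays`.
#' @export
summarize_by_group <- function(assays, group_keys = "genotype") {
  stopifnot(length(assays) >= 1L,
            all(vapply(assays, inherits, TRUE, "phototaxis_assay")))
  if (!all(group_keys %in% c("genotype", "sex"))) {
    stop("group_keys must be a subset of c(\"genotype\", \"sex\")", call. = FALSE)
  }
  df <- data.frame(
    genotype = vapply(assays, `[[`, "", "genotype"),
    sex = vapply(assays, `[[`, "", "sex"),
    fraction = vapply(assays, score_assay, 0),
    stringsAsFactors = FALSE
  )
  key <- interaction(df[group_keys], drop = TRUE, sep = "|")
  out <- do.call(rbind, lapply(split(df, key), function(d) {
    row <- d[1, group_keys, drop = FALSE]
    row$mean_fraction <- mean(d$fraction)
    row$sd <- if (nrow(d) > 1) stats::sd(d$fraction) else NA_real_
    row$n_assays <- nrow(d)
    row
  }))
  rownames(out) <- NULL
  out
}

#' Read and write phototaxis assay tables
#'
#' CSV columns: `assay_id, genotype, sex, n_total, tube0, tube1, tube2,
#' tube3`.
#'
#' @param assays A list of [phototaxis_assay()] objects.
#' @param path CSV path.
#' @return `write_assays_csv` returns `path` invisibly; `read_assays_csv`
#'   returns a list of assays.
#' @export
write_assays_csv <- function(assays, path) {
  df <- do.call(rbind, lapply(assays, function(a) {
    data.frame(assay_id = a$assay_id, genotype = a$genotype, sex = a$sex,
               n_total = a$n_total, tube0 = a$tube_counts[1],
               tube1 = a$tube_counts[2], tube2 = a$tube_counts[3],
               tube3 = a$tube_counts[4], stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assays_csv
#' @export
read_assays_csv <- function(path) {
  if (!file.exists(path)) stop("assay CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    a <- phototaxis_assay(df$assay_id[i], df$genotype[i], df$sex[i],
                          c(df$tube0[i], df$tube1[i], df$tube2[i], df$tube3[i]))
    if (a$n_total != df$n_total[i]) {
      stop(sprintf("assay %s: tube counts sum to %d but n_total is %d",
                   a$assay_id, a$n_total, df$n_total[i]), call. = FALSE)
    }
    a
  })
}
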