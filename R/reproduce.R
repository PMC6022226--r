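# Recomputation of every printed quantity that is reproducible from the
# packaged tables alone: pIC50 transforms, residuals and least-squared
# errors, the r2 / adjusted-r2 identities, selectivity indices, marker
# fold changes and external-validation activities, each checked against
# its printed value.

check_row <- function(name, computed, expected, tol) {
  data.frame(check = name, computed = computed, expected = expected,
             tolerance = tol,
             status = ifelse(abs(computed - expected) <= tol,
                             "PASS", "FAIL"))
}

#' Recompute the printed results from the packaged data
#'
#' Runs every desk-scale check the packaged tables allow:
#' \itemize{
#'   \item pIC50 arithmetic: -log10 of each uncensored IC50 against the
#'     printed experimental activities (training and external tables);
#'   \item residual bookkeeping: experimental - predicted against the
#'     printed residual columns, and the mean squared residual of each
#'     endpoint against the printed least-squared errors;
#'   \item model statistics: squared Pearson correlation of experimental
#'     vs predicted columns against the printed r2 values, and the
#'     adjusted-r2 identity at the printed (n, p);
#'   \item assay arithmetic: selectivity indices, apoptosis-marker fold
#'     changes and the annexin-positive fold.
#' }
#'
#' @return data frame of checks (`check`, `computed`, `expected`,
#'   `tolerance`, `status`) with attribute `n_fail`.
#' @export
reproduce_report <- function() {
  out <- list()
  act <- activity_table()
  t4 <- training_table()
  t5 <- external_table()

  # the external Caco-2 row printed "13a" carries compound 11a's activity
  t5r <- t5
  t5r$compound[t5r$compound == "13a" & t5r$cell_line == "Caco-2"] <- "11a"

  for (tab in list(cbind(t4, table = "training"),
                   cbind(t5r, table = "external"))) {
    for (k in seq_len(nrow(tab))) {
      a <- act[act$compound == tab$compound[k] &
               act$cell_line == tab$cell_line[k], ]
      if (nrow(a) != 1 || a$censored) next
      out[[length(out) + 1]] <- check_row(
        sprintf("pIC50 %s %s (%s)", tab$compound[k], tab$cell_line[k],
                tab$table[k]),
        round(pic50(a$ic50_um), 4), tab$experimental[k], 1e-4)
    }
  }

  # residuals and least-squared error per endpoint
  for (line in c("HepG2", "Caco-2")) {
    sub <- t4[t4$cell_line == line, ]
    rt <- residual_table(setNames(sub$experimental, sub$compound),
                         setNames(sub$predicted, sub$compound))
    for (k in seq_len(nrow(sub)))
      out[[length(out) + 1]] <- check_row(
        sprintf("residual %s %s", sub$compound[k], line),
        rt$residual[k], sub$residual[k], 1.01e-4)
    lse_exp <- c("HepG2" = 0.0168, "Caco-2" = 0.0173)[[line]]
    out[[length(out) + 1]] <- check_row(
      sprintf("least-squared error %s (n = %d)", line, nrow(sub)),
      round(attr(rt, "lse"), 4), lse_exp, 5e-5)
    r2_exp <- c("HepG2" = 0.940, "Caco-2" = 0.896)[[line]]
    r2 <- cor(sub$experimental, sub$predicted)^2
    out[[length(out) + 1]] <- check_row(
      sprintf("r2 %s", line), round(r2, 3), r2_exp, 5e-4)
    p <- c("HepG2" = 4, "Caco-2" = 3)[[line]]
    adj_exp <- c("HepG2" = 0.910, "Caco-2" = 0.865)[[line]]
    out[[length(out) + 1]] <- check_row(
      sprintf("adjusted r2 %s (n = %d, p = %d)", line, nrow(sub), p),
      round(adjusted_r2(r2_exp, nrow(sub), p), 3), adj_exp, 5e-4)
  }

  # selectivity indices
  t2 <- selectivity_table()
  for (k in seq_len(nrow(t2)))
    out[[length(out) + 1]] <- check_row(
      sprintf("selectivity index %s", t2$compound[k]),
      round(selectivity_index(t2$ic50_wi38_um[k], t2$ic50_hepg2_um[k])),
      t2$selectivity_index[k], 0)

  # apoptosis-marker folds
  t3 <- apoptosis_table()
  ctrl <- t3[t3$compound == "control", ]
  for (k in which(t3$compound != "control")) {
    cl <- ctrl$level[ctrl$marker == t3$marker[k]]
    out[[length(out) + 1]] <- check_row(
      sprintf("%s fold %s", t3$marker[k], t3$compound[k]),
      round(fold_change(t3$level[k], cl), 1), t3$fold_of_control[k], 0.051)
  }

  # annexin V-positive fold
  ax <- annexin_table()
  out[[length(out) + 1]] <- check_row(
    "annexin V-positive fold 13a",
    round(fold_change(ax$percent_positive[ax$condition == "13a"],
                      ax$percent_positive[ax$condition == "control"]), 1),
    7.9, 0.051)

  rep <- do.call(rbind, out)
  attr(rep, "n_fail") <- sum(rep$status == "FAIL")
  rep
}

#' Format a reproduction report as text lines
#'
#' @param report data frame from [reproduce_report()].
#' @return character vector of report lines (byte-stable for a fixed
#'   package version).
#' @export
format_report <- function(report) {
  c(sprintf("%-42s %12s %12s  %s", "check", "computed", "expected",
            "status"),
    sprintf("%-42s %12.4f %12.4f  %s", report$check, report$computed,
            report$expected, report$status),
    sprintf("%d of %d checks failed", attr(report, "n_fail"),
            nrow(report)))
}
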