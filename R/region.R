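# Feasible-region and contour computations: where (PPV, NPV) pairs at a
# given prevalence invert to a valid (sensitivity, specificity) pair, on a
# grid in predictive-value axes or on logarithmically spaced NNT axes.
#
# Under the contra-Bayes algebra the feasible region in predictive-value
# axes is exactly the open rectangle {PPV > prevalence, NPV > 1 - prevalence}
# whose corner (prevalence, 1 - prevalence) is the image of every
# uninformative test; the contours sensitivity = prevalence and
# specificity = 1 - prevalence both pass through that corner.

#' Evaluate the contra-Bayes inversion on a grid
#'
#' Builds a grid of candidate (PPV, NPV) points -- directly in
#' predictive-value axes, or via `NNT_Pos = 1/PPV` (x) and
#' `NNT_Neg = 1/(1 - NPV)` (y) on logarithmically spaced NNT axes -- and
#' inverts each node.  Nodes where the inversion is infeasible are flagged
#' with the violated inequality and carry `NA` sensitivity/specificity; they
#' are never clamped into range.
#'
#' @param prevalence Prevalence of `BestToAct`, strictly inside (0, 1).
#' @param axes `"pv"` for predictive-value axes (x = PPV, y = NPV, uniform
#'   in \[0, 1\]) or `"nnt"` for NNT axes (x = NNT_Pos, y = NNT_Neg,
#'   log-spaced between `nnt_range[1]` and `nnt_range[2]`).
#' @param resolution Number of grid points per axis, `>= 2`; default 201.
#' @param nnt_range Endpoints of the log-spaced NNT axes, default
#'   `c(1.05, 1000)`.
#' @return A `region_grid`: a data frame with columns `x`, `y`, `ppv`,
#'   `npv`, `sensitivity`, `specificity`, `feasible`, `reason`, and
#'   attributes `prevalence` and `axes`.
#' @examples
#' g <- compute_region(0.05, resolution = 41)
#' table(g$feasible)
#' @export
compute_region <- function(prevalence, axes = c("pv", "nnt"),
                           resolution = 201, nnt_range = c(1.05, 1000)) {
  check_prevalence(prevalence)
  axes <- match.arg(axes)
  check_number(resolution, "resolution")
  if (resolution < 2) stop("resolution must be at least 2", call. = FALSE)

  if (axes == "pv") {
    x <- seq(0, 1, length.out = resolution)
    y <- seq(0, 1, length.out = resolution)
    grid <- expand.grid(x = x, y = y, KEEP.OUT.ATTRS = FALSE)
    grid$ppv <- grid$x
    grid$npv <- grid$y
  } else {
    stopifnot(length(nnt_range) == 2L, nnt_range[1] > 1,
              nnt_range[2] > nnt_range[1])
    x <- exp(seq(log(nnt_range[1]), log(nnt_range[2]),
                 length.out = resolution))
    y <- x
    grid <- expand.grid(x = x, y = y, KEEP.OUT.ATTRS = FALSE)
    grid$ppv <- 1 / grid$x
    grid$npv <- 1 - 1 / grid$y
  }

  odds <- prevalence / (1 - prevalence)
  # margins on the odds scale; sign is all that matters for feasibility
  margin_pos <- ifelse(grid$ppv == 1, Inf,
                       grid$ppv / (1 - grid$ppv) - odds)
  margin_neg <- ifelse(grid$npv == 0, -Inf,
                       odds - (1 - grid$npv) / grid$npv)
  grid$feasible <- margin_pos > 0 & margin_neg > 0
  grid$reason <- ""
  grid$reason[margin_pos <= 0] <- "ppv_not_above_prevalence"
  grid$reason[margin_neg <= 0] <- "npv_not_above_complement"
  grid$reason[margin_pos <= 0 & margin_neg <= 0] <- "both"

  grid$sensitivity <- NA_real_
  grid$specificity <- NA_real_
  ok <- grid$feasible
  grid$sensitivity[ok] <- contra_sn_(grid$ppv[ok], grid$npv[ok], prevalence)
  grid$specificity[ok] <- contra_sp_(grid$ppv[ok], grid$npv[ok], prevalence)

  structure(grid, prevalence = prevalence, axes = axes,
            class = c("region_grid", "data.frame"))
}

#' @export
print.region_grid <- function(x, ...) {
  cat("Contra-Bayes region grid: ", nrow(x), " nodes, prevalence ",
      attr(x, "prevalence"), ", ", attr(x, "axes"), " axes, ",
      sum(x$feasible), " feasible\n", sep = "")
  invisible(x)
}

#' Locus of predictive values for tests with equal sensitivity and specificity
#'
#' For `s` on a uniform grid in \[0.5, 1\] computes the forward-Bayes image
#' of a test with `sensitivity = specificity = s` at the given prevalence.
#' The endpoint `s = 0.5` is a purely random test and maps to
#' `(PPV, NPV) = (prevalence, 1 - prevalence)`; `s = 1` is a perfect test
#' and maps to `(1, 1)`.
#'
#' @param prevalence Prevalence of `BestToAct`, strictly inside (0, 1).
#' @param n_points Number of grid points, `>= 2`; default 101.
#' @return A data frame with columns `sn_sp`, `ppv`, `npv`.
#' @examples
#' equal_sn_sp_locus(0.05, n_points = 6)  # the lettered points A-F
#' @export
equal_sn_sp_locus <- function(prevalence, n_points = 101) {
  check_prevalence(prevalence)
  check_number(n_points, "n_points")
  if (n_points < 2) stop("n_points must be at least 2", call. = FALSE)
  s <- seq(0.5, 1, length.out = n_points)
  pv <- bayes_forward(s, s, prevalence)
  data.frame(sn_sp = s, ppv = pv$ppv, npv = pv$npv)
}

#' Export a region grid to CSV
#'
#' Writes the grid as a tidy CSV with columns `x`, `y`, `ppv`, `npv`,
#' `sensitivity`, `specificity`, `feasible`, `reason` plus header comment
#' lines (`# prevalence=...`, `# axes=...`) so that [read_region()]
#' round-trips the object.
#'
#' @param grid A `region_grid` from [compute_region()].
#' @param path File path to write to.
#' @return The path, invisibly.
#' @export
export_region <- function(grid, path) {
  stopifnot(inherits(grid, "region_grid"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  writeLines(c(paste0("# prevalence=", format(attr(grid, "prevalence"),
                                              digits = 17)),
               paste0("# axes=", attr(grid, "axes"))), con)
  utils::write.csv(as.data.frame(grid), con, row.names = FALSE)
  invisible(path)
}

#' Read a region grid written by [export_region()]
#'
#' @param path File path to read.
#' @return A `region_grid` equal (up to numeric round-trip precision) to the
#'   exported one.
#' @export
read_region <- function(path) {
  header <- readLines(path, n = 2L)
  if (length(header) < 2L || !all(startsWith(header, "# ")))
    stop("'", path, "' does not look like an exported region grid",
         call. = FALSE)
  prevalence <- as.numeric(sub("# prevalence=", "", header[1L], fixed = TRUE))
  axes <- sub("# axes=", "", header[2L], fixed = TRUE)
  grid <- utils::read.csv(path, skip = 2L)
  grid$reason[is.na(grid$reason)] <- ""
  structure(grid, prevalence = prevalence, axes = axes,
            class = c("region_grid", "data.frame"))
}

#' Plot a region grid (optional thin layer over the exported data)
#'
#' Shades feasible and infeasible nodes and overlays sensitivity and
#' specificity contours.  Requires ggplot2; the tested artifact is the grid
#' data itself, this plot is a convenience.
#'
#' @param grid A `region_grid` from [compute_region()].
#' @param bins Number of contour bins per characteristic, default 9.
#' @return A ggplot object.
#' @export
plot_region <- function(grid, bins = 9) {
  stopifnot(inherits(grid, "region_grid"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_region() needs the ggplot2 package", call. = FALSE)
  df <- as.data.frame(grid)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$reason), alpha = 0.4) +
    ggplot2::geom_contour(data = df[grid$feasible, ],
                          ggplot2::aes(z = .data$sensitivity),
                          colour = "red", bins = bins) +
    ggplot2::geom_contour(data = df[grid$feasible, ],
                          ggplot2::aes(z = .data$specificity),
                          colour = "blue", bins = bins) +
    ggplot2::labs(
      x = if (attr(grid, "axes") == "pv") "PPV" else "NNT_Pos",
      y = if (attr(grid, "axes") == "pv") "NPV" else "NNT_Neg",
      fill = "infeasibility",
      title = paste0("Contra-Bayes feasible region, prevalence ",
                     attr(grid, "prevalence")))
  if (attr(grid, "axes") == "nnt")
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}
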