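#' Per-acinus perfusion summary
#'
#' Extracts acinar flows, gravitational heights (cm, zero at the most
#' dependent acinus) and mean-normalized flows (% of mean) from a solved
#' state, together with the headline aggregates: gravitational gradient `G`,
#' coefficient of variation `COV`, and left/right lung flow split.
#'
#' @param state A `network_state` or `coupled_run`.
#' @param n_bins Height bins for the SD profile.
#' @return A `perfusion_summary`: `acini` tibble
#'   (`id, lung, flow, height_cm, norm_flow`) plus `G`, `COV`, `split`,
#'   `sd_profile` and `posture`.
#' @export
perfusion_summary <- function(state, n_bins = 10) {
  if (inherits(state, "coupled_run")) state <- state$state
  if (is.null(state$acini)) stop("state has no acini")
  ac <- state$acini
  df <- tibble::tibble(
    id = ac$id, lung = ac$lung, flow = ac$flow,
    height_cm = (ac$height - min(ac$height)) * 100,
    norm_flow = 100 * ac$flow / mean(ac$flow)
  )
  gravity_on <- state$posture != "zero_g"
  structure(list(
    acini = df,
    G = if (gravity_on) gravitational_gradient(df) else NA_real_,
    COV = coefficient_of_variation(df),
    split = lung_flow_split(df),
    sd_profile = sd_height_profile(df, n_bins = n_bins),
    posture = state$posture
  ), class = "perfusion_summary")
}

#' @export
print.perfusion_summary <- function(x, ...) {
  cat("<perfusion_summary> posture:", x$posture, "\n")
  cat("  G:  ", if (is.na(x$G)) "not reported (zero gravity)" else
    paste0(signif(x$G, 3), " %/cm"), "\n")
  cat("  COV:", signif(x$COV, 3), "%\n")
  cat("  split (% of flow):",
      paste(x$split$lung, signif(x$split$fraction_pct, 4),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Gravitational gradient of perfusion
#'
#' Ordinary least-squares slope of mean-normalized acinar flow (%, mean 100)
#' against gravitational height (cm), negated so that positive `G` means more
#' flow in the dependent (low-height) lung. Undefined without gravity: pass
#' `gravity_on = FALSE` (or a zero-g summary) to obtain `NA`.
#'
#' @param data Data frame with columns `flow` (or `norm_flow`) and
#'   `height_cm`.
#' @param gravity_on Set `FALSE` for zero-gravity runs, where no gradient is
#'   reported.
#' @return Slope in %/cm (scalar), or `NA` when gravity is off.
#' @export
gravitational_gradient <- function(data, gravity_on = TRUE) {
  if (!gravity_on) return(NA_real_)
  h <- data$height_cm
  if (length(unique(h)) < 2) stop("need at least two distinct heights")
  nf <- if ("norm_flow" %in% names(data)) data$norm_flow else
    100 * data$flow / mean(data$flow)
  -unname(stats::coef(stats::lm(nf ~ h))[2])
}

#' Coefficient of variation of acinar perfusion
#'
#' `100 * SD / mean` over acini, sample (n-1) standard deviation.
#'
#' @param data Data frame with a `flow` column (or a bare numeric vector).
#' @return COV in percent.
#' @export
coefficient_of_variation <- function(data) {
  flows <- if (is.data.frame(data)) data$flow else data
  if (!length(flows)) stop("empty input")
  m <- mean(flows)
  if (m <= 0) stop("mean flow must be positive")
  100 * stats::sd(flows) / m
}

#' Left/right lung flow split
#'
#' @param data Data frame with `flow` and `lung` columns (every acinus must
#'   be labeled).
#' @return Tibble `lung, flow, fraction_pct`; fractions sum to 100.
#' @export
lung_flow_split <- function(data) {
  if (anyNA(data$lung)) stop("unlabeled acinus")
  out <- dplyr::summarise(dplyr::group_by(data, .data$lung),
                          flow = sum(.data$flow), .groups = "drop")
  out$fraction_pct <- 100 * out$flow / sum(out$flow)
  out
}

#' Standard deviation of perfusion by height
#'
#' Bins acini into equal-width gravitational height bins and reports the
#' sample SD of mean-normalized flow per bin. When a `reference` summary is
#' supplied (e.g. an uncoupled 1D run of the same geometry), the difference
#' in per-bin SD (data minus reference) is added.
#'
#' @param data Data frame with `height_cm` and `norm_flow` (or `flow`).
#' @param n_bins Number of equal-width bins (>= 2).
#' @param reference Optional second data frame binned identically.
#' @return Tibble `bin, h_lo, h_hi, h_mid, n, sd_norm_flow` (plus
#'   `sd_reference`, `sd_difference` when a reference is given); empty bins
#'   carry `NA`.
#' @export
sd_height_profile <- function(data, n_bins = 10, reference = NULL) {
  stopifnot(n_bins >= 2)
  norm <- function(d) if ("norm_flow" %in% names(d)) d$norm_flow else
    100 * d$flow / mean(d$flow)
  h <- data$height_cm
  brk <- seq(min(h), max(h), length.out = n_bins + 1)
  bin_of <- function(hh) pmin(pmax(findInterval(hh, brk, rightmost.closed = TRUE), 1L),
                              n_bins)
  sd_by_bin <- function(d) {
    b <- bin_of(d$height_cm)
    v <- norm(d)
    vapply(seq_len(n_bins), function(k) {
      x <- v[b == k]
      if (length(x) >= 2) stats::sd(x) else NA_real_
    }, numeric(1))
  }
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    h_lo = brk[-length(brk)], h_hi = brk[-1],
    h_mid = (brk[-length(brk)] + brk[-1]) / 2,
    n = tabulate(bin_of(h), n_bins),
    sd_norm_flow = sd_by_bin(data)
  )
  if (!is.null(reference)) {
    out$sd_reference <- sd_by_bin(reference)
    out$sd_difference <- out$sd_norm_flow - out$sd_reference
  }
  out
}

#' Tidy a perfusion summary
#'
#' Per-acinus tibble with normalized flows and heights.
#' @param x A `perfusion_summary`.
#' @param ... Unused.
#' @method tidy perfusion_summary
#' @export
tidy.perfusion_summary <- function(x, ...) {
  x$acini
}

#' One-row summary of perfusion metrics
#'
#' @param x A `perfusion_summary`.
#' @param ... Unused.
#' @method glance perfusion_summary
#' @export
glance.perfusion_summary <- function(x, ...) {
  right <- x$split$fraction_pct[x$split$lung == "right"]
  tibble::tibble(posture = x$posture, G_pct_per_cm = x$G, COV_pct = x$COV,
                 right_fraction_pct = if (length(right)) right else NA_real_,
                 n_acini = nrow(x$acini))
}

#' Perfusion-versus-height plot
#'
#' Scatter of mean-normalized acinar flow against gravitational height with
#' the OLS trend, annotated with G and COV — the standard way these model
#' outputs are displayed.
#'
#' @param object A `perfusion_summary`.
#' @param alpha Point transparency.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perfusion_summary
#' @export
autoplot.perfusion_summary <- function(object, alpha = 0.15, ...) {
  lab <- paste0(
    if (!is.na(object$G)) paste0("G = ", signif(object$G, 3), " %/cm; ") else "",
    "COV = ", signif(object$COV, 3), "%")
  ggplot2::ggplot(object$acini,
                  ggplot2::aes(x = .data$norm_flow, y = .data$height_cm)) +
    ggplot2::geom_point(alpha = alpha, size = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         orientation = "y", linewidth = 0.5) +
    ggplot2::labs(x = "acinar perfusion (% of mean)", y = "gravitational height (cm)",
                  title = paste("Acinar perfusion,", object$posture),
                  subtitle = lab) +
    ggplot2::theme_minimal()
}
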