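## S3 methods for a solved case (class "ip_nodule").

#' @export
print.ip_nodule <- function(x, ...) {
  s <- x$scenario
  cat("Intraperitoneal chemotherapy nodule simulation\n")
  cat("  case:    ", s$label, "\n", sep = "")
  cat(sprintf("  mesh:     %s, %d nodes\n", x$mesh$mode, x$mesh$n_nodes))
  cat(sprintf("  IFP_max:  %.2f Pa   IFV_max: %.3g m/s\n",
              x$pressure$IFP_max, x$velocity$IFV_max))
  for (i in seq_len(nrow(x$metrics)))
    cat(sprintf("  %s: LP50 = %.3f, APD = %.3f mm, PD%% = %.2f, Pe = %.3g\n",
                x$metrics$axis[i], x$metrics$LP50[i], x$metrics$APD_mm[i],
                x$metrics$PD_percent[i], x$metrics$Pe[i]))
  invisible(x)
}

#' Summarize a solved nodule case
#'
#' @param object an `ip_nodule` from [run_case()].
#' @param ... unused.
#' @return The object, invisibly, after printing the transient metric
#'   table (evaluated at `t_end`), the steady-state table and solver
#'   diagnostics.
#' @export
summary.ip_nodule <- function(object, ...) {
  print(object)
  cat(sprintf("\nTransient metrics (t = %g s):\n", object$transport$t_end))
  print(object$metrics, digits = 4, row.names = FALSE)
  cat("\nSteady-state metrics:\n")
  print(object$metrics_steady, digits = 4, row.names = FALSE)
  cat(sprintf("\nresidual drop %.2e; fluid imbalance %.2e; timings: flow %.2fs, transport %.2fs\n",
              object$pressure$residuals[2] / max(object$pressure$residuals[1], 1e-300),
              fluid_budget(object$pressure)$rel_imbalance,
              object$timings[["setup_flow"]], object$timings[["transport"]]))
  invisible(object)
}

#' Key metrics of a solved case as a named vector
#'
#' @param object an `ip_nodule`.
#' @param ... unused.
#' @return Named numeric vector: IFP_max (Pa), IFV_max (m/s), then per
#'   axis LP50, APD (mm), PD% and Pe.
#' @export
coef.ip_nodule <- function(object, ...) {
  m <- object$metrics
  out <- c(IFP_max_Pa = object$pressure$IFP_max,
           IFV_max_m_s = object$velocity$IFV_max)
  for (i in seq_len(nrow(m))) {
    nm <- m$axis[i]
    v <- c(m$LP50[i], m$APD_mm[i], m$PD_percent[i], m$Pe[i])
    names(v) <- paste0(c("LP50.", "APD_mm.", "PD_percent.", "Pe."), nm)
    out <- c(out, v)
  }
  out
}

#' Evaluate solved fields along an axis
#'
#' Linear interpolation of the pressure or concentration profile at
#' arbitrary distances from the nodule centre.
#'
#' @param object an `ip_nodule`.
#' @param distance distances from the centre, m.
#' @param axis `"LA"` or `"SA"`.
#' @param what `"concentration"` (mol/m^3, at `t_end`), `"pressure"` (Pa)
#'   or `"steady_concentration"`.
#' @param ... unused.
#' @return Numeric vector of field values.
#' @export
predict.ip_nodule <- function(object, distance, axis = "LA",
                              what = c("concentration", "pressure",
                                       "steady_concentration"), ...) {
  what <- match.arg(what)
  field <- switch(what, concentration = object$transport,
                  pressure = object$pressure,
                  steady_concentration = object$steady)
  prof <- extract_profile(field, axis = axis,
                          n_samples = max(400, object$control$n_profile))
  if (any(distance < 0 | distance > prof$half_length * (1 + 1e-9)))
    stop("predict.ip_nodule: distance outside [0, half_length]")
  stats::approx(prof$pos, prof$values, xout = distance, rule = 2)$y
}

#' Plot pressure and concentration profiles of a solved case
#'
#' Two panels: normalized interstitial pressure and normalized drug
#' concentration against normalized distance from the centre, one curve
#' per axis, with the IC50 threshold marked.
#'
#' @param x an `ip_nodule`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.ip_nodule <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  axes <- names(x$mesh$axes)
  cols <- c(LA = "black", SA = "grey40")[seq_along(axes)]
  pmax_ <- x$pressure$IFP_max
  profs_p <- lapply(axes, function(a) extract_profile(x$pressure, axis = a))
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1.05),
                 xlab = "normalized distance from centre",
                 ylab = expression(P[i] / IFP[max]), main = x$scenario$label)
  for (i in seq_along(axes))
    graphics::lines(profs_p[[i]]$npos, profs_p[[i]]$values / pmax_,
                    col = cols[i], lwd = 2, lty = i)
  graphics::legend("bottomleft", legend = axes, col = cols,
                   lty = seq_along(axes), lwd = 2, bty = "n")
  C0 <- x$transport$C0
  profs_c <- lapply(axes, function(a) extract_profile(x$transport, axis = a))
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1.05),
                 xlab = "normalized distance from centre",
                 ylab = expression(C / C[0]),
                 main = sprintf("t = %g s", x$transport$t_end))
  for (i in seq_along(axes))
    graphics::lines(profs_c[[i]]$npos, profs_c[[i]]$values / C0,
                    col = cols[i], lwd = 2, lty = i)
  graphics::abline(h = x$scenario$drug$IC50 / C0, col = "red3", lty = 3)
  graphics::mtext(sprintf("IC50/C0 = %.2g", x$scenario$drug$IC50 / C0),
                  side = 3, line = -1.2, cex = 0.8, col = "red3")
  invisible(x)
}
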