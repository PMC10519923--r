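#' Frame timing scheme
#'
#' @param n_frames number of frames (default 8).
#' @param frame_duration duration of each frame in minutes (default 6).
#' @param half_life isotope half-life in minutes (default 109.77, F-18);
#'   used only in `decay_only` simulation mode.
#' @return object of class `frame_scheme` with derived `frame_starts` and
#'   total scan time.
#' @export
frame_scheme <- function(n_frames = 8, frame_duration = 6, half_life = 109.77) {
  if (n_frames < 1 || frame_duration <= 0) stop_input("invalid frame scheme")
  structure(list(n_frames = as.integer(n_frames),
                 frame_duration = frame_duration,
                 half_life = half_life,
                 frame_starts = (seq_len(n_frames) - 1) * frame_duration,
                 total_time = n_frames * frame_duration),
            class = "frame_scheme")
}

#' Feng-model arterial input function
#'
#' Plasma activity curve of the tri-exponential Feng model,
#' `Cp(t) = (A1 t - A2 - A3) exp(-l1 t) + A2 exp(-l2 t) + A3 exp(-l3 t)`,
#' with `Cp(0) = 0`. The default amplitudes and decay rates are the standard
#' published FDG parameter set (`A = (851.1, 21.88, 20.81)` activity units,
#' `lambda = (4.1339, 0.1191, 0.01043)` 1/min); the absolute activity scale is
#' arbitrary here because simulated sinograms are rescaled to a count budget.
#'
#' @param t_grid nonnegative, increasing time grid in minutes.
#' @param A amplitudes `(A1, A2, A3)`.
#' @param lambda decay rates `(l1, l2, l3)` in 1/min.
#' @return plasma activity on `t_grid`.
#' @export
feng_input_function <- function(t_grid, A = c(851.1, 21.88, 20.81),
                                lambda = c(4.1339, 0.1191, 0.01043)) {
  if (any(t_grid < 0)) stop_input("input function times must be nonnegative")
  (A[1] * t_grid - A[2] - A[3]) * exp(-lambda[1] * t_grid) +
    A[2] * exp(-lambda[2] * t_grid) + A[3] * exp(-lambda[3] * t_grid)
}

## cumulative trapezoid integral of y over t, same length as y
cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

## causal convolution (exp(-alpha t) * y)(t) on a (possibly nonuniform) grid,
## via the exact interval recursion for trapezoid-sampled y
exp_convolve <- function(t, y, alpha) {
  n <- length(t)
  out <- numeric(n)
  for (i in 2:n) {
    dt <- t[i] - t[i - 1]
    e <- exp(-alpha * dt)
    out[i] <- out[i - 1] * e + dt / 2 * (y[i] + e * y[i - 1])
  }
  out
}

#' Irreversible two-tissue-compartment time-activity curve
#'
#' Tissue activity of the irreversible (k4 = 0) two-tissue-compartment model
#' driven by a plasma input `Cp`:
#' `C_T(t) = K1 k3 / (k2 + k3) * int_0^t Cp
#'         + K1 k2 / (k2 + k3) * (exp(-(k2 + k3) t) conv Cp) + Fv Cp(t)`.
#' The first term is the irreversibly trapped compartment (nondecreasing for
#' nonnegative `Cp`), the second the reversible free compartment.
#'
#' @param params a [kinetic_params()].
#' @param cp plasma activity sampled on `t_grid`.
#' @param t_grid increasing time grid in minutes (fine enough for quadrature;
#'   a step of ~0.01 min is ample).
#' @return tissue activity on `t_grid`.
#' @export
tac_2tc <- function(params, cp, t_grid) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$k2 + params$k3 <= 0)
    stop_input("degenerate model: k2 + k3 must be positive")
  if (length(cp) != length(t_grid)) stop_input("cp and t_grid length mismatch")
  if (params$K1 == 0 && params$Fv == 0) return(numeric(length(t_grid)))
  a <- params$k2 + params$k3
  trapped <- params$K1 * params$k3 / a * cumtrapz(t_grid, cp)
  free <- params$K1 * params$k2 / a * exp_convolve(t_grid, cp, a)
  pmax(trapped + free + params$Fv * cp, 0)
}

#' Average a fine-grid curve over acquisition frames
#'
#' @param t_grid fine time grid in minutes.
#' @param values curve values on `t_grid`.
#' @param scheme a [frame_scheme()].
#' @return numeric vector of per-frame time averages.
#' @export
frame_average <- function(t_grid, values, scheme) {
  vapply(seq_len(scheme$n_frames), function(f) {
    t0 <- scheme$frame_starts[f]
    sel <- t_grid >= t0 & t_grid <= t0 + scheme$frame_duration
    if (!any(sel)) stop_input("time grid does not cover frame %d", f)
    mean(values[sel])
  }, numeric(1))
}

## fine simulation grid covering the whole scan
kinetic_time_grid <- function(scheme, dt = 0.01) {
  seq(0, scheme$total_time, by = dt)
}

#' Dynamic activity volume from a phantom
#'
#' Builds the 4-D activity distribution `[row, col, slice, frame]` a dynamic
#' acquisition would see. In `decay_only` mode the base phantom decays with
#' the isotope half-life and each frame holds the frame-averaged decay factor
#' (count-accumulation physics of long frames, rather than midpoint
#' sampling). In `kinetic` mode each labelled tissue follows its
#' two-tissue-compartment curve under the Feng input function, frame-averaged
#' the same way.
#'
#' @param phantom either a 3-D activity array (`decay_only`) or a
#'   `phantom_spec` from [make_brain_like_phantom()] (`kinetic`).
#' @param scheme a [frame_scheme()].
#' @param mode `"decay_only"` or `"kinetic"`.
#' @param input_function function of a time grid returning plasma activity;
#'   defaults to [feng_input_function()].
#' @return 4-D nonnegative array `[row, col, slice, frame]`.
#' @export
make_dynamic_phantom <- function(phantom, scheme, mode = c("decay_only", "kinetic"),
                                 input_function = feng_input_function) {
  mode <- match.arg(mode)
  if (mode == "decay_only") {
    if (!is.array(phantom) || length(dim(phantom)) != 3L)
      stop_input("decay_only mode expects a 3-D activity array")
    lam <- log(2) / scheme$half_life
    f0 <- scheme$frame_starts
    dur <- scheme$frame_duration
    fac <- if (is.finite(lam) && lam > 0)
      exp(-lam * f0) * (1 - exp(-lam * dur)) / (lam * dur)
    else rep(1, scheme$n_frames)
    out <- array(0, c(dim(phantom), scheme$n_frames))
    for (f in seq_len(scheme$n_frames)) out[, , , f] <- phantom * fac[f]
    return(out)
  }
  if (!inherits(phantom, "phantom_spec"))
    stop_input("kinetic mode expects a phantom_spec")
  tg <- kinetic_time_grid(scheme)
  cp <- input_function(tg)
  labs <- sort(unique(as.vector(phantom$labels)))
  labs <- labs[labs != 0]
  out <- array(0, c(dim(phantom$labels), scheme$n_frames))
  for (lb in labs) {
    p <- phantom$tissue_params[[as.character(lb)]]
    if (is.null(p)) stop_input("no kinetic parameters for label %d", lb)
    tac <- frame_average(tg, tac_2tc(p, cp, tg), scheme)
    sel <- phantom$labels == lb
    for (f in seq_len(scheme$n_frames)) {
      fr <- out[, , , f]
      fr[sel] <- tac[f]
      out[, , , f] <- fr
    }
  }
  out
}
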