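# Warmup-cosine learning-rate schedule and the AdamW optimizer.

#' Warmup-cosine schedule configuration
#'
#' Linear warmup from 0 to `eta_max` over `warmup_steps`, then half-cosine
#' decay to 0 at `total_steps`. Time is measured in optimizer steps.
#'
#' @param eta_max Peak learning rate (default 5e-4).
#' @param warmup_steps Warmup duration T_w in steps.
#' @param total_steps Total duration T in steps.
#' @param weight_decay Decoupled weight-decay coefficient (default 1e-4).
#' @return An object of class `bilight_schedule`.
#' @export
schedule_config <- function(eta_max = 5e-4, warmup_steps, total_steps,
                            weight_decay = 1e-4) {
  stopifnot(eta_max > 0, warmup_steps > 0, total_steps > warmup_steps)
  structure(list(eta_max = eta_max, warmup_steps = warmup_steps,
                 total_steps = total_steps, weight_decay = weight_decay),
            class = "bilight_schedule")
}

#' Learning rate at a step
#'
#' `t < T_w`: `eta_max * t / T_w`; `t >= T_w`:
#' `eta_max / 2 * (1 + cos(pi (t - T_w) / (T - T_w)))`. Continuous at
#' `t = T_w`, equal to 0 at both `t = 0` and `t = T`, and maximal
#' (`eta_max`) exactly at the warmup boundary.
#'
#' @param t Step (scalar or vector), `0 <= t <= total_steps`.
#' @param cfg A `bilight_schedule`.
#' @return Learning rate(s).
#' @export
lr_at <- function(t, cfg) {
  stopifnot(inherits(cfg, "bilight_schedule"))
  if (any(t < 0) || any(t > cfg$total_steps))
    stop("step t must lie in [0, total_steps]", call. = FALSE)
  Tw <- cfg$warmup_steps; Tt <- cfg$total_steps
  ifelse(t < Tw,
         cfg$eta_max * t / Tw,
         0.5 * cfg$eta_max * (1 + cos(pi * (t - Tw) / (Tt - Tw))))
}

#' Export the schedule curve
#'
#' Writes the full step-by-step learning-rate curve as a two-column CSV
#' (`step`, `lr`) for plotting.
#'
#' @param cfg A `bilight_schedule`.
#' @param path Output CSV path.
#' @param by Step stride (default 1).
#' @export
export_schedule <- function(cfg, path, by = 1L) {
  t <- seq(0L, cfg$total_steps, by = by)
  utils::write.csv(data.frame(step = t, lr = lr_at(t, cfg)), path,
                   row.names = FALSE)
  invisible(path)
}

# Parameters receiving decoupled weight decay: projection matrices and
# conv kernels. Biases, normalization affines and the GeM exponent are
# exempt.
DECAYED_PARAMS <- c("a_W1", "b_W1", "a_eca", "b_eca",
                    "Wg", "WA", "WB", "Wh", "Wc")

adamw_init <- function(par) {
  trainable <- names(par)[vapply(par, function(x)
    isTRUE(attr(x, "trainable")), logical(1))]
  list(m = lapply(par[trainable], function(x) x * 0),
       v = lapply(par[trainable], function(x) x * 0),
       t = 0L, trainable = trainable)
}

# One decoupled-weight-decay Adam step. Decay multiplies the weights
# directly (not the gradients) and skips the exempt parameters.
adamw_step <- function(par, grads, state, lr, weight_decay = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in state$trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    newv <- par[[nm]] - lr * upd
    if (nm %in% DECAYED_PARAMS) newv <- newv - lr * weight_decay * par[[nm]]
    par[[nm]] <- tr(newv, TRUE)
  }
  list(par = par, state = state)
}
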