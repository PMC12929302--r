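#' Snapshot-ensemble cyclical learning-rate schedule configuration
#'
#' The defaults encode the reference training configuration: six cycles of
#' 1000 epochs, a learning rate starting at 0.1 that decays to a constant
#' plateau of 0.01 over the last 100 epochs of each cycle, and four
#' retained checkpoints per cycle — 24 ensemble members in total. The
#' constant-rate plateau keeps the optimiser from collapsing to a single
#' solution, and the high restart rate at each cycle start drives
#' between-cycle diversity.
#'
#' @param n_cycles number of cycles (default 6).
#' @param cycle_epochs epochs per cycle (default 1000).
#' @param lr_start learning rate at each cycle start (default 0.1).
#' @param lr_floor plateau learning rate (default 0.01).
#' @param plateau_epochs length of the constant-rate phase (default 100).
#' @param keep_last checkpoints retained per cycle, from the end of the
#'   plateau (default 4).
#' @param decay `"poly"` (polynomial, exponent 0.9 — the convention of the
#'   segmentation framework the schedule pairs with) or `"linear"`.
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(n_cycles = 6L, cycle_epochs = 1000L,
                            lr_start = 0.1, lr_floor = 0.01,
                            plateau_epochs = 100L, keep_last = 4L,
                            decay = c("poly", "linear")) {
  decay <- match.arg(decay)
  if (plateau_epochs >= cycle_epochs)
    stop("plateau_epochs must be smaller than cycle_epochs", call. = FALSE)
  if (lr_floor >= lr_start)
    stop("lr_floor must be below lr_start", call. = FALSE)
  if (any(c(n_cycles, cycle_epochs, plateau_epochs, keep_last) < 1))
    stop("all counts must be >= 1", call. = FALSE)
  structure(list(n_cycles = as.integer(n_cycles),
                 cycle_epochs = as.integer(cycle_epochs),
                 lr_start = lr_start, lr_floor = lr_floor,
                 plateau_epochs = as.integer(plateau_epochs),
                 keep_last = as.integer(keep_last), decay = decay),
            class = "schedule_config")
}

#' Learning rate at a global epoch of the cyclical schedule
#'
#' Epochs are 0-based and global; the position within a cycle is the epoch
#' modulo the cycle length. With `D = cycle_epochs - plateau_epochs`, the
#' rate in the decreasing phase (`e < D`) is
#' `lr_floor + (lr_start - lr_floor) * (1 - e/D)^0.9` (or linear when
#' configured), and `lr_floor` throughout the plateau — continuous at the
#' junction. The schedule is non-increasing within a cycle and exactly
#' periodic across cycles.
#'
#' @param epoch 0-based global epoch index (vectorised); must lie in
#'   `[0, n_cycles * cycle_epochs)`.
#' @param cfg a [schedule_config()].
#' @return Learning rate(s) in `[lr_floor, lr_start]`.
#' @export
learning_rate <- function(epoch, cfg = schedule_config()) {
  total <- cfg$n_cycles * cfg$cycle_epochs
  if (any(epoch < 0 | epoch >= total | epoch != floor(epoch)))
    stop(sprintf("epoch must be an integer in [0, %d)", total), call. = FALSE)
  e <- epoch %% cfg$cycle_epochs
  D <- cfg$cycle_epochs - cfg$plateau_epochs
  frac <- pmax(0, 1 - e / D)
  shape <- if (cfg$decay == "poly") frac^0.9 else frac
  ifelse(e >= D, cfg$lr_floor, cfg$lr_floor + (cfg$lr_start - cfg$lr_floor) * shape)
}

#' Global epochs at which ensemble checkpoints are retained
#'
#' Per cycle, the `keep_last` final epochs — all inside the constant-rate
#' plateau, so every retained checkpoint was taken at the floor learning
#' rate. The default configuration yields 6 x 4 = 24 checkpoints.
#'
#' @param cfg a [schedule_config()] with `keep_last <= plateau_epochs`.
#' @return Ascending integer vector of 0-based global epoch indices of
#'   length `n_cycles * keep_last`.
#' @export
checkpoint_epochs <- function(cfg = schedule_config()) {
  if (cfg$keep_last > cfg$plateau_epochs)
    stop("keep_last cannot exceed plateau_epochs", call. = FALSE)
  unlist(lapply(seq_len(cfg$n_cycles) - 1L, function(cyc) {
    cyc * cfg$cycle_epochs +
      seq(cfg$cycle_epochs - cfg$keep_last, cfg$cycle_epochs - 1L)
  }))
}
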