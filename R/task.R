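# Eight-condition gambling task.  Conditions 1-6 oppose a 50/50 two-slot
# gamble to a sure option; conditions 7-8 oppose two sure options, where
# the "gamble" column denotes the ambiguous one.  Slot types per condition:
#   1: gain/loss vs 0          2: gain/amb-loss vs 0
#   3: amb-gain/loss vs 0      4: gain/0 vs sure gain
#   5: amb-gain/0 vs sure gain 6: gain/0 vs amb sure gain
#   7: amb sure gain vs sure gain   8: amb sure loss vs sure loss
.cond_spec <- list(
  list(g1 = "gain",     g2 = "loss",     sure = "zero",     p = 0.5),
  list(g1 = "gain",     g2 = "amb_loss", sure = "zero",     p = 0.5),
  list(g1 = "amb_gain", g2 = "loss",     sure = "zero",     p = 0.5),
  list(g1 = "gain",     g2 = "zero",     sure = "gain",     p = 0.5),
  list(g1 = "amb_gain", g2 = "zero",     sure = "gain",     p = 0.5),
  list(g1 = "gain",     g2 = "zero",     sure = "amb_gain", p = 0.5),
  list(g1 = "amb_gain", g2 = NA,         sure = "gain",     p = 1.0),
  list(g1 = "amb_loss", g2 = NA,         sure = "loss",     p = 1.0)
)

.gain_grid <- seq(10, 90, by = 5)
.loss_grid <- seq(-90, -10, by = 5)

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# n values spanning a grid: evenly spaced grid positions, shuffled.
.stratified_sample <- function(grid, n) {
  v <- grid[round(seq(1, length(grid), length.out = n))]
  sample(v)
}

#' Build reproducible task schedules
#'
#' Generates the 138-trial, 7-block schedule for each subject.  Trial
#' values (magnitudes, latent values of ambiguous slots, assignment of
#' trials to blocks) are identical across subjects; only the within-block
#' trial order differs, re-randomized per subject.  Gain magnitudes are
#' sampled on the 10..90 grid in steps of 5 (losses -90..-10), stratified
#' to span the grid within each condition.  In condition 4 the sure amount
#' is half the risky gain (snapped to the grid), so the two options have
#' equal expected value; conditions 5-6 use sure amounts spanning the
#' lower half of the grid to keep choices informative.
#'
#' @param seed Integer seed controlling all randomness.
#' @param subjects Number of subjects.
#' @param counts Per-condition trial counts (length 8, must sum to 138 by
#'   default; any total is accepted as long as it matches `n_trials`).
#' @param n_trials,n_blocks Schedule shape; defaults 138 and 7.
#' @return Data frame, one row per trial per subject, ordered by subject
#'   then trial position, with columns `subject`, `block`, `trial`,
#'   `condition`, `gamble_p`, `g1_value`, `g1_amb`, `g2_value`, `g2_amb`,
#'   `sure_value`, `sure_amb`, `latent_gain`, `latent_loss`.  Ambiguous
#'   slots have `NA` magnitude and their latent true value in the latent
#'   column of the matching valence.
#' @export
build_schedule <- function(seed, subjects = 1,
                           counts = c(18, 18, 18, 17, 17, 17, 17, 16),
                           n_trials = 138, n_blocks = 7) {
  stopifnot(length(counts) == 8, all(counts > 0))
  if (sum(counts) != n_trials)
    stop("condition counts sum to ", sum(counts),
         " but the schedule requires ", n_trials, " trials")
  .with_seed(seed, {
    base <- .build_base_trials(counts)
    # fixed assignment of trials to blocks, shared across subjects
    sizes <- rep(n_trials %/% n_blocks, n_blocks)
    extra <- n_trials - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    base <- base[sample(nrow(base)), ]
    base$block <- rep(seq_len(n_blocks), sizes)
    latent_gain <- sample(.gain_grid, 1)
    latent_loss <- sample(.loss_grid, 1)
    out <- vector("list", subjects)
    for (s in seq_len(subjects)) {
      ord <- unlist(lapply(split(seq_len(n_trials), base$block),
                           sample), use.names = FALSE)
      d <- base[ord, ]
      d$subject <- s
      d$trial <- seq_len(n_trials)
      out[[s]] <- d
    }
    res <- do.call(rbind, out)
    res$latent_gain <- latent_gain
    res$latent_loss <- latent_loss
    rownames(res) <- NULL
    res[, c("subject", "block", "trial", "condition", "gamble_p",
            "g1_value", "g1_amb", "g2_value", "g2_amb",
            "sure_value", "sure_amb", "latent_gain", "latent_loss")]
  })
}

.build_base_trials <- function(counts) {
  rows <- vector("list", 8)
  for (cond in 1:8) {
    n <- counts[cond]
    cs <- .cond_spec[[cond]]
    slot_vals <- function(type, role) {
      if (is.na(type) || type == "zero") return(rep(0, n))
      if (type %in% c("amb_gain", "amb_loss")) return(rep(NA_real_, n))
      grid <- if (type == "gain") .gain_grid else .loss_grid
      .stratified_sample(grid, n)
    }
    g1 <- slot_vals(cs$g1)
    g2 <- slot_vals(cs$g2)
    sure <- slot_vals(cs$sure)
    if (cond == 4) {
      # equal expected value: sure = gain / 2 snapped to grid
      sure <- pmin(90, pmax(10, 5 * round(g1 / 10)))
    } else if (cond %in% c(5, 6)) {
      # sure amounts span the lower half of the gain grid, matching the
      # EV range of a gain/zero gamble
      sure_grid <- seq(10, 50, by = 5)
      if (cond == 5) sure <- .stratified_sample(sure_grid, n)
    }
    rows[[cond]] <- data.frame(
      condition = cond, gamble_p = cs$p,
      g1_value = g1, g1_amb = identical(substr(cs$g1, 1, 3), "amb"),
      g2_value = if (is.na(cs$g2)) NA_real_ else g2,
      g2_amb = if (is.na(cs$g2)) NA else identical(substr(cs$g2, 1, 3), "amb"),
      sure_value = sure,
      sure_amb = identical(substr(cs$sure, 1, 3), "amb")
    )
  }
  do.call(rbind, rows)
}

# valence of the ambiguous slot(s) in a condition, used for reveals
.amb_valence <- function(type) {
  if (identical(type, "amb_gain")) "gain" else
    if (identical(type, "amb_loss")) "loss" else "none"
}

#' Resolve the outcome of one trial
#'
#' For a chosen 50/50 gamble one slot pays with probability 0.5; sure
#' options pay their single slot.  If the paying slot is ambiguous its
#' latent true value is paid out and its valence is flagged as revealed
#' (the running score discloses the hidden magnitude), which is what
#' drives the learning models.
#'
#' @param trial One schedule row (data frame with the `build_schedule`
#'   columns).
#' @param chose_gamble Logical; `TRUE` if the gamble/ambiguous option was
#'   chosen.
#' @return List with `outcome` (points) and `reveal` (`"none"`, `"gain"`,
#'   or `"loss"`).
#' @export
resolve_outcome <- function(trial, chose_gamble) {
  cond <- trial$condition
  cs <- .cond_spec[[cond]]
  if (chose_gamble) {
    slot <- if (cs$p < 1 && stats::runif(1) < 0.5) 2L else 1L
    type <- if (slot == 1L) cs$g1 else cs$g2
    val <- if (slot == 1L) trial$g1_value else trial$g2_value
  } else {
    type <- cs$sure
    val <- trial$sure_value
  }
  rv <- .amb_valence(type)
  if (rv == "gain") val <- trial$latent_gain
  if (rv == "loss") val <- trial$latent_loss
  list(outcome = as.numeric(val), reveal = rv)
}

# delimited IO --------------------------------------------------------------

#' Read or write schedules and choice data as tab-delimited text
#'
#' Missing magnitudes (ambiguous slots) are written as empty fields, never
#' as 0.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_table_tsv` returns a data frame.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = "",
                    stringsAsFactors = FALSE)
}
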