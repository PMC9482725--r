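#' Parameter designs for the natural-history engines
#'
#' A *design* is a named numeric vector of the free (calibrated) parameters
#' of one engine, carrying a block label per parameter.
#'
#' The event-based engine has 8 parameters: four Johnson SB shape pairs
#' `(delta_i, gamma_i)`, `i = 0..3`, governing in turn the per-individual
#' adenoma-risk multiplier, the dwell from progressive non-advanced adenoma
#' (`P_NON`) to advanced (`ADV`), the dwell from non-progressive
#' non-advanced adenoma (`NP_NON`) to `ADV`, and the dwell from `ADV` to
#' cancer (`CRC`).  Each pair is its own block (the sensitivity order used
#' by the sequential procedures is `risk`, `p_non`, `np_non`, `adv`).
#'
#' The cycle-based engine has 19 parameters in three blocks along the
#' adenoma-carcinoma sequence: `initiation` (7: base 3-month occurrence
#' probability, five age-band multipliers, and the log-sd of a lognormal
#' per-individual risk multiplier), `early` (6: four per-cycle stage-advance
#' probabilities through early adenoma stages I-IV plus two multiplicative
#' modifiers applied to all of them), and `advanced` (6: two advanced-stage
#' advance probabilities, the per-cycle cancer-transition probability, and
#' one multiplicative modifier for each of the three).
#'
#' @param x named numeric vector of length 8 (`event_design`) or 19
#'   (`cycle_design`); names must match the canonical layout (see
#'   [baseline_design()] for the canonical names in order).
#' @return The validated design vector with class `"event_design"` or
#'   `"cycle_design"` and a `"blocks"` attribute (named character vector of
#'   block labels).
#' @seealso [baseline_design()], [design_space()]
#' @examples
#' d <- baseline_design("event", "male")
#' design_blocks(d)
#' @name designs
NULL

event_param_names <- function() {
  c("delta0", "gamma0", "delta1", "gamma1",
    "delta2", "gamma2", "delta3", "gamma3")
}

event_param_blocks <- function() {
  stats::setNames(rep(c("risk", "p_non", "np_non", "adv"), each = 2),
                  event_param_names())
}

cycle_param_names <- function() {
  c("init_base", paste0("init_mult_", 1:5), "init_risk_sd",
    paste0("early_adv_", 1:4), "early_mod_sex", "early_mod_size",
    "adv_prog_1", "adv_prog_2", "cancer_prob",
    "adv_mod_1", "adv_mod_2", "cancer_mod")
}

cycle_param_blocks <- function() {
  stats::setNames(rep(c("initiation", "early", "advanced"), c(7, 6, 6)),
                  cycle_param_names())
}

#' @rdname designs
#' @export
event_design <- function(x) {
  nm <- event_param_names()
  if (length(x) != 8L) stop("an event design has exactly 8 parameters",
                            call. = FALSE)
  if (!is.null(names(x)) && !setequal(names(x), nm)) {
    stop("event design names must be: ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  x <- if (is.null(names(x))) stats::setNames(as.numeric(x), nm) else
    as.numeric(x[nm]) |> stats::setNames(nm)
  deltas <- x[grep("^delta", nm)]
  if (any(!is.finite(x))) stop("design values must be finite", call. = FALSE)
  if (any(deltas <= 0)) stop("all delta_i must be > 0", call. = FALSE)
  structure(x, class = "event_design", blocks = event_param_blocks())
}

#' @rdname designs
#' @export
cycle_design <- function(x) {
  nm <- cycle_param_names()
  if (length(x) != 19L) stop("a cycle design has exactly 19 parameters",
                             call. = FALSE)
  if (!is.null(names(x)) && !setequal(names(x), nm)) {
    stop("cycle design names must match the canonical 19-parameter layout",
         call. = FALSE)
  }
  x <- if (is.null(names(x))) stats::setNames(as.numeric(x), nm) else
    as.numeric(x[nm]) |> stats::setNames(nm)
  if (any(!is.finite(x))) stop("design values must be finite", call. = FALSE)
  if (any(x[c("init_base", paste0("early_adv_", 1:4),
              "adv_prog_1", "adv_prog_2", "cancer_prob")] < 0)) {
    stop("cycle probabilities must be nonnegative", call. = FALSE)
  }
  structure(x, class = "cycle_design", blocks = cycle_param_blocks())
}

#' @rdname designs
#' @export
design_blocks <- function(x) attr(x, "blocks")

#' Packaged baseline parameter designs
#'
#' The prior point estimates used as the centre of every search range and as
#' the ground truth of all synthetic-target self-tests.  They were chosen
#' once so that each engine's simulated prevalences are of the same order as
#' published screening-colonoscopy prevalence (advanced adenoma roughly
#' 4-10%, cancerous neoplasia roughly 0.3-2.5% across ages 55-79), with
#' males above females; they are not estimates of any real population.
#'
#' @param engine `"event"` (8 parameters) or `"cycle"` (19 parameters).
#' @param sex `"male"` or `"female"`.
#' @return An `event_design` or `cycle_design`.
#' @examples
#' baseline_design("cycle", "female")
#' @export
baseline_design <- function(engine = c("event", "cycle"),
                            sex = c("male", "female")) {
  engine <- match.arg(engine)
  sex <- match.arg(sex)
  if (engine == "event") {
    x <- c(delta0 = 0.80, gamma0 = 0.20,   # risk multiplier on (0, 1)
           delta1 = 1.20, gamma1 = 0.60,   # P_NON -> ADV dwell, median ~11 y
           delta2 = 1.00, gamma2 = -0.70,  # NP_NON -> ADV dwell, median ~40 y
           delta3 = 0.50, gamma3 = -2.00)  # ADV -> CRC dwell, slow tail
    if (sex == "female") {
      # lower risk multipliers and slightly slower progression
      x["gamma0"] <- 0.75
      x["gamma1"] <- 0.75
      x["gamma3"] <- -1.85
    }
    event_design(x)
  } else {
    x <- c(init_base = 0.002,
           init_mult_1 = 0.5, init_mult_2 = 1.5, init_mult_3 = 2.5,
           init_mult_4 = 3.5, init_mult_5 = 4.0,
           init_risk_sd = 0.5,
           early_adv_1 = 0.040, early_adv_2 = 0.035,
           early_adv_3 = 0.030, early_adv_4 = 0.025,
           early_mod_sex = 1.0, early_mod_size = 1.0,
           adv_prog_1 = 0.02, adv_prog_2 = 0.02, cancer_prob = 0.02,
           adv_mod_1 = 1.0, adv_mod_2 = 1.0, cancer_mod = 1.0)
    if (sex == "female") {
      x["init_base"] <- 0.0015
      x["early_mod_sex"] <- 0.9
    }
    cycle_design(x)
  }
}

#' Build a search space around a baseline design
#'
#' The default range per parameter is the baseline value +/- 20%.  For the
#' event engine the `delta_i` ranges are widened to +/- 40% by default,
#' because the prevalence responses are considerably more sensitive to
#' `delta` than to the paired `gamma`.  Positive parameters are searched in
#' log coordinates and per-cycle probabilities in logit coordinates, so the
#' unconstrained simplex phase can never propose an invalid design.
#'
#' @param design an `event_design` or `cycle_design` (the baseline).
#' @param rel half-width of the relative range around the baseline
#'   (0.2 = +/- 20%).
#' @param rel_delta half-width used for event-engine `delta_i` parameters.
#' @return A data.frame with class `"design_space"` and columns `name`,
#'   `baseline`, `lower`, `upper`, `block`, `transform`.
#' @examples
#' sp <- design_space(baseline_design("event", "male"))
#' sp[, c("name", "lower", "upper", "block")]
#' @export
design_space <- function(design, rel = 0.2, rel_delta = 0.4) {
  stopifnot(inherits(design, c("event_design", "cycle_design")))
  v <- as.numeric(design)
  nm <- names(design)
  half <- rep(rel, length(v))
  transform <- rep("log", length(v))
  if (inherits(design, "event_design")) {
    is_delta <- grepl("^delta", nm)
    half[is_delta] <- rel_delta
    transform[!is_delta] <- "identity"   # gammas may cross zero
  } else {
    probs <- nm %in% c("init_base", paste0("early_adv_", 1:4),
                       "adv_prog_1", "adv_prog_2", "cancer_prob")
    transform[probs] <- "logit"
  }
  lower <- pmin(v * (1 - half), v * (1 + half))
  upper <- pmax(v * (1 - half), v * (1 + half))
  if (any(lower >= upper)) {
    stop("degenerate search range (baseline value 0?) for: ",
         paste(nm[lower >= upper], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(name = nm, baseline = v, lower = lower, upper = upper,
                    block = unname(design_blocks(design)),
                    transform = transform, stringsAsFactors = FALSE)
  class(out) <- c("design_space", "data.frame")
  attr(out, "engine") <- if (inherits(design, "event_design")) "event" else
    "cycle"
  out
}

# Rebuild a typed design from a bare numeric vector in space order.
space_design <- function(space, values) {
  x <- stats::setNames(as.numeric(values), space$name)
  if (attr(space, "engine") == "event") event_design(x) else cycle_design(x)
}

# Natural <-> unconstrained coordinates for the simplex phase.
to_unconstrained <- function(space, values) {
  tr <- space$transform
  out <- as.numeric(values)
  out[tr == "log"] <- log(out[tr == "log"])
  lg <- tr == "logit"
  if (any(lg)) {
    p <- pmin(pmax(out[lg], 1e-12), 1 - 1e-12)
    out[lg] <- log(p / (1 - p))
  }
  out
}

from_unconstrained <- function(space, values) {
  tr <- space$transform
  out <- as.numeric(values)
  out[tr == "log"] <- exp(out[tr == "log"])
  lg <- tr == "logit"
  out[lg] <- 1 / (1 + exp(-out[lg]))
  out
}
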