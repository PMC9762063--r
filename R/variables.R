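# Variable inventory: name, concept, measurement tier, type and causal role.
#
# A variable table is the contract shared by the synthetic generator, the
# constraint builder and the data-integration layer.  Tiers are the study's
# measurement waves T0 (baseline), T1 (3 months), T2 (6 months, short-term)
# and T3 (12 months, long-term); demographics and the intervention indicator
# are "static" (measured once, before any wave).

TIERS <- c("static", "T0", "T1", "T2", "T3")
ROLES <- c("demographic", "baseline", "intervention", "determinant", "outcome")

#' Declare one variable of the integrated dataset
#'
#' @param name column identifier, e.g. `"intention_T2"`.
#' @param concept study-overarching concept label, e.g. `"intention"`.
#' @param tier one of `"static"`, `"T0"`, `"T1"`, `"T2"`, `"T3"`.
#' @param role one of `"demographic"`, `"baseline"`, `"intervention"`,
#'   `"determinant"`, `"outcome"`.  Baseline is the role of every tier-T0
#'   measurement; determinants/outcomes are the post-baseline waves.
#' @param vtype `"discrete"` or `"continuous"`.
#' @param levels character vector of levels (discrete variables; >= 2).
#' @param range numeric length-2 admissible range (continuous variables);
#'   use infinities for unbounded scales.
#' @return a one-row `data.frame` with list-columns `levels` and `range`.
#' @export
variable_spec <- function(name, concept, tier, role, vtype,
                          levels = NULL, range = c(-Inf, Inf)) {
  abort_if(!is_string(name), "variable `name` must be a single string")
  tier <- match.arg(tier, TIERS)
  role <- match.arg(role, ROLES)
  vtype <- match.arg(vtype, c("discrete", "continuous"))
  if (vtype == "discrete") {
    abort_if(length(levels) < 2L, sprintf("discrete variable '%s' needs >= 2 levels", name))
    levels <- as.character(levels)
    range <- c(NA_real_, NA_real_)
  } else {
    abort_if(length(range) != 2L || any(is.na(range)) || range[1] >= range[2],
             sprintf("continuous variable '%s' needs a valid (min, max) range", name))
    levels <- character(0)
  }
  if (role %in% c("demographic", "intervention"))
    abort_if(tier != "static", sprintf("'%s': demographics/intervention are static", name))
  if (tier == "T0")
    abort_if(role != "baseline", sprintf("'%s': tier-T0 measurements carry the baseline role", name))
  if (role == "baseline")
    abort_if(tier != "T0", sprintf("'%s': the baseline role is reserved for tier T0", name))
  out <- data.frame(name = name, concept = concept, tier = tier, role = role,
                    vtype = vtype, stringsAsFactors = FALSE)
  out$levels <- list(levels)
  out$range <- list(as.numeric(range))
  out
}

#' Bind variable specs into a variable table
#'
#' @param ... one-row specs from [variable_spec()], or data.frames of them.
#' @return a `pabn_variables` data.frame, one row per variable.
#' @export
variable_table <- function(...) {
  vt <- do.call(rbind, list(...))
  abort_if(anyDuplicated(vt$name) > 0L, "duplicate variable names")
  class(vt) <- c("pabn_variables", "data.frame")
  vt
}

# integer time index used by the temporal rule; static nodes have none
tier_index <- function(tier) {
  idx <- match(tier, c("T0", "T1", "T2", "T3"))
  ifelse(tier == "static", NA_integer_, idx - 1L)
}

var_row <- function(variables, name) {
  i <- match(name, variables$name)
  abort_if(any(is.na(i)), sprintf("unknown variable(s): %s",
                                  paste(name[is.na(i)], collapse = ", ")))
  variables[i, , drop = FALSE]
}

is_discrete_var <- function(variables, name) var_row(variables, name)$vtype == "discrete"

#' @export
print.pabn_variables <- function(x, ...) {
  cat(sprintf("Variable table: %d variables (%d discrete, %d continuous)\n",
              nrow(x), sum(x$vtype == "discrete"), sum(x$vtype == "continuous")))
  for (r in split(x, x$role)[unique(x$role)])
    cat(sprintf("  %-12s %s\n", r$role[1], paste(r$name, collapse = ", ")))
  invisible(x)
}
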