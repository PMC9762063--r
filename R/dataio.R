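# Concept-scale construction, recoding, multi-study integration and
# subpopulation filtering.
#
# Missing marker: NA in memory; empty field on CSV write; empty field or
# "NA" accepted on read.

#' Concept scale from item scores
#'
#' The scale value is the mean of the observed items, valid while the
#' fraction of missing items does not exceed `max_missing_frac`
#' (inclusive -- an "allowed maximum" of 25% admits exactly 25%).
#'
#' @param item_scores numeric vector of item scores, `NA` for missing.
#' @param max_missing_frac allowed missing fraction in `[0, 1)` (default 0.25).
#' @return the scale mean, or `NA` when too many items are missing.
#' @export
compute_concept_scale <- function(item_scores, max_missing_frac = 0.25) {
  abort_if(length(item_scores) == 0L, "empty item list")
  abort_if(!(max_missing_frac >= 0 && max_missing_frac < 1),
           "max_missing_frac must be in [0, 1)")
  frac <- mean(is.na(item_scores))
  if (frac > max_missing_frac) NA_real_ else mean(item_scores, na.rm = TRUE)
}

#' Recode item scores onto a unipolar scale
#'
#' Affine map from a source `(min, max)` range to a target range (e.g. a
#' bipolar -2..2 item onto 1..5); missing values pass through.
#'
#' @param item_scores numeric vector.
#' @param source_scale,target_scale numeric length-2 `(min, max)` pairs.
#' @return recoded numeric vector.
#' @export
recode_unipolar <- function(item_scores, source_scale, target_scale) {
  abort_if(length(source_scale) != 2L || length(target_scale) != 2L,
           "scales are (min, max) pairs")
  abort_if(source_scale[1L] == source_scale[2L], "degenerate source scale")
  target_scale[1L] + (item_scores - source_scale[1L]) *
    diff(target_scale) / diff(source_scale)
}

#' Bundle one study's records
#'
#' @param study_id study identifier.
#' @param records data.frame of participant rows (study-overarching
#'   variable names).
#' @param measured character vector of the variables this study measured;
#'   defaults to the record columns.
#' @return a `pabn_study` object.
#' @export
study_dataset <- function(study_id, records, measured = names(records)) {
  abort_if(!is_string(as.character(study_id)), "study_id must be a single id")
  extra <- setdiff(names(records), measured)
  for (v in extra)
    abort_if(any(!is.na(records[[v]])),
             sprintf("study %s: non-missing values in unmeasured '%s'", study_id, v))
  structure(list(study_id = as.character(study_id), records = records,
                 measured = measured), class = "pabn_study")
}

#' Integrate several study datasets into one table
#'
#' The integrated table spans the union of the studies' variables; a cell is
#' missing iff the study never measured that variable or the source value
#' was itself missing.  Every non-missing source cell is conserved
#' bit-exactly, and each record keeps its study of origin.
#'
#' @param datasets list of `pabn_study` objects.
#' @param variables optional `pabn_variables` table declaring the union
#'   inventory (checked against the data when given).
#' @return a `pabn_integrated` object: `records` (data.frame), `provenance`
#'   (study id per record), `variables`.
#' @export
integrate_studies <- function(datasets, variables = NULL) {
  abort_if(!length(datasets), "no datasets")
  all_vars <- unique(unlist(lapply(datasets, function(d) names(d$records))))
  if (!is.null(variables)) {
    abort_if(!all(all_vars %in% variables$name),
             "study variable not declared in the variable table")
    all_vars <- intersect(variables$name, all_vars)   # canonical order
  }
  # conflicting type declarations across studies are an integration error
  for (v in all_vars) {
    kinds <- unique(unlist(lapply(datasets, function(d)
      if (v %in% names(d$records)) class(d$records[[v]])[1L])))
    kinds[kinds %in% c("integer", "numeric")] <- "numeric"
    abort_if(length(unique(kinds)) > 1L,
             sprintf("conflicting types for '%s' across studies", v))
  }
  blocks <- lapply(datasets, function(d) {
    rec <- d$records
    for (v in setdiff(all_vars, names(rec))) rec[[v]] <- NA
    rec[all_vars]
  })
  # harmonize factor levels across studies before binding
  for (v in all_vars) {
    if (any(vapply(blocks, function(b) is.factor(b[[v]]), TRUE))) {
      levs <- unique(unlist(lapply(blocks, function(b) levels(b[[v]]))))
      blocks <- lapply(blocks, function(b) {
        b[[v]] <- factor(as.character(b[[v]]), levels = levs); b
      })
    }
  }
  records <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  provenance <- rep(vapply(datasets, `[[`, "", "study_id"),
                    vapply(datasets, function(d) nrow(d$records), 0L))
  structure(list(records = records, provenance = provenance,
                 variables = variables), class = "pabn_integrated")
}

#' @export
print.pabn_integrated <- function(x, ...) {
  cat(sprintf("Integrated dataset: %d records x %d variables from %d studies; %.1f%% cells missing\n",
              nrow(x$records), ncol(x$records),
              length(unique(x$provenance)),
              100 * mean(is.na(as.matrix(x$records)))))
  invisible(x)
}

#' Filter a subpopulation and drop constant variables
#'
#' Keeps the records where `variable == value` (or where `predicate`
#' returns `TRUE`).  Any variable that is constant over the kept records --
#' in particular the stratifying demographic itself -- is dropped from the
#' table and the variable list, since a constant cannot enter the model.
#'
#' @param data a `pabn_integrated` object.
#' @param variable demographic column to stratify on.
#' @param value level defining the stratum.
#' @param predicate alternatively, a function `records -> logical`.
#' @return the filtered `pabn_integrated` with attribute `dropped` listing
#'   removed constant variables.
#' @export
filter_subpopulation <- function(data, variable = NULL, value = NULL,
                                 predicate = NULL) {
  abort_if(!inherits(data, "pabn_integrated"), "need a pabn_integrated dataset")
  keep <- if (!is.null(predicate)) predicate(data$records)
          else {
            abort_if(!variable %in% names(data$records),
                     sprintf("unknown variable '%s'", variable))
            !is.na(data$records[[variable]]) & data$records[[variable]] == value
          }
  abort_if(sum(keep) == 0L, "predicate selects zero records")
  rec <- data$records[keep, , drop = FALSE]
  rownames(rec) <- NULL
  constant <- vapply(rec, function(x) length(unique(x[!is.na(x)])) <= 1L, TRUE)
  dropped <- names(rec)[constant]
  rec <- rec[, !constant, drop = FALSE]
  vars <- data$variables
  if (!is.null(vars)) {
    vars <- vars[vars$name %in% names(rec), , drop = FALSE]
    class(vars) <- c("pabn_variables", "data.frame")
  }
  out <- structure(list(records = rec, provenance = data$provenance[keep],
                        variables = vars), class = "pabn_integrated")
  attr(out, "dropped") <- dropped
  out
}

#' Write / read an integrated dataset as CSV
#'
#' Missing cells are written as empty fields; a `study_id` column carries
#' provenance.  A JSON sidecar (written by [write_variables()]) restores
#' the declared types on read.
#'
#' @param data a `pabn_integrated` object.
#' @param path CSV path.
#' @param variables a `pabn_variables` table used to restore column types.
#' @return `write_integrated`: `path` invisibly; `read_integrated`: the
#'   dataset.
#' @export
write_integrated <- function(data, path) {
  out <- cbind(study_id = data$provenance, data$records)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_integrated
#' @export
read_integrated <- function(path, variables = NULL) {
  raw <- utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE,
                         colClasses = "character")
  prov <- raw$study_id
  rec <- raw[setdiff(names(raw), "study_id")]
  for (v in names(rec)) {
    if (!is.null(variables) && v %in% variables$name) {
      row <- var_row(variables, v)
      rec[[v]] <- if (row$vtype == "discrete")
        factor(rec[[v]], levels = row$levels[[1L]])
      else as.numeric(rec[[v]])
    } else {
      num <- suppressWarnings(as.numeric(rec[[v]]))
      rec[[v]] <- if (all(is.na(num) == is.na(rec[[v]]))) num
                  else factor(rec[[v]])
    }
  }
  structure(list(records = rec, provenance = prov, variables = variables),
            class = "pabn_integrated")
}

#' Write / read a variable inventory as a JSON schema
#' @param variables a `pabn_variables` table.
#' @param path file path.
#' @return `write_variables`: `path` invisibly; `read_variables`: the table.
#' @export
write_variables <- function(variables, path) {
  lst <- lapply(seq_len(nrow(variables)), function(i) {
    v <- variables[i, ]
    list(name = v$name, concept = v$concept, tier = v$tier, role = v$role,
         vtype = v$vtype, levels = v$levels[[1L]], range = v$range[[1L]])
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_variables
#' @export
read_variables <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  do.call(variable_table, lapply(lst, function(v) {
    if (identical(v$vtype, "discrete"))
      variable_spec(v$name, v$concept, v$tier, v$role, v$vtype,
                    levels = as.character(unlist(v$levels)))
    else
      variable_spec(v$name, v$concept, v$tier, v$role, v$vtype,
                    range = as.numeric(unlist(v$range)))
  }))
}
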