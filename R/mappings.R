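#' Load mapping tables
#'
#' Reads the five mapping CSVs (`ad_mapping.csv`, `rst_mapping.csv`,
#' `compatibility.csv`, `medication_mapping.csv`, `mixture_mapping.csv`) plus
#' the rate-unit conversion table (`units.csv`) from a directory and
#' validates their structural invariants. The tables bundled with the
#' package ([default_mappings()]) are synthetic: they reproduce the schema,
#' the leveled orderings and the category counts of an institutional mapping
#' (18 airway-device categories on levels 1-9, 7 respiratory-support-therapy
#' categories on levels 1-7, 8 administration-route categories, 2
#' techniques) with representative free-text entries, not any hospital's
#' actual vocabulary.
#'
#' @param dir Directory containing the mapping CSVs.
#' @param validate Validate structural invariants after loading (default
#'   `TRUE`).
#' @return An object of class `alarm_mappings`: a named list of tibbles
#'   `ad`, `rst`, `compatibility`, `medication`, `mixture`, `units`.
#' @export
load_mappings <- function(dir, validate = TRUE) {
  need <- c(
    ad = "ad_mapping.csv", rst = "rst_mapping.csv",
    compatibility = "compatibility.csv", medication = "medication_mapping.csv",
    mixture = "mixture_mapping.csv", units = "units.csv"
  )
  paths <- file.path(dir, need)
  missing <- !file.exists(paths)
  if (any(missing)) {
    rlang::abort(paste0("Missing mapping file(s): ", paste(need[missing], collapse = ", ")))
  }
  m <- lapply(paths, function(p) {
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  })
  names(m) <- names(need)
  m$rst$ad_category[is.na(m$rst$ad_category)] <- ""
  m <- structure(m, class = "alarm_mappings")
  if (validate) {
    rep <- validate_mappings(m)
    if (!all(rep$ok)) {
      rlang::abort(paste0(
        "Mapping validation failed:\n",
        paste("-", rep$check[!rep$ok], ":", rep$detail[!rep$ok], collapse = "\n")
      ))
    }
  }
  m
}

#' @rdname load_mappings
#' @export
default_mappings <- function() {
  load_mappings(system.file("extdata", "mappings", package = "icualarms"))
}

#' @export
print.alarm_mappings <- function(x, ...) {
  cat("<alarm_mappings>\n")
  for (nm in setdiff(names(x), "units")) {
    cat("  ", nm, ": ", nrow(x[[nm]]), " rows\n", sep = "")
  }
  invisible(x)
}

#' Validate mapping tables
#'
#' Checks the structural invariants of a mapping bundle: the printed
#' category counts (18 airway-device categories on levels 1-9, 7
#' respiratory-support-therapy categories on levels 1-7, 8 route categories,
#' 2 techniques), level anchors (level 1 is "no airway device", level 9 the
#' endotracheal tube / tracheal cannula), exactly one annotation-flagged row
#' per airway-device string, the all-`FALSE` level-1 row of the
#' compatibility table (level 1 is formally not a respiratory support
#' therapy), the absence of level 0 from the therapy mapping (level 0 exists
#' only for standby handling), and the rule that stop/decrease relevance is
#' never granted for the low-saturation condition.
#'
#' @param mappings An `alarm_mappings` object (see [load_mappings()]).
#' @return A tibble with columns `check`, `ok`, `detail`.
#' @export
validate_mappings <- function(mappings) {
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, ok = ok, detail = detail
    )
  }

  ad <- mappings$ad
  cats <- unique(ad$ad_category[ad$ad_level >= 1])
  add("ad: 18 categories", length(cats) == 18,
      paste0("found ", length(cats)))
  add("ad: levels within 0-9", all(ad$ad_level %in% 0:9),
      paste0("levels: ", paste(sort(unique(ad$ad_level)), collapse = ",")))
  add("ad: level 1 is no_ad",
      all(ad$ad_category[ad$ad_level == 1] == "no_ad"), "")
  add("ad: level 9 anchors",
      all(c("endotracheal_tube", "tracheal_cannula") %in%
            ad$ad_category[ad$ad_level == 9]), "")
  flags <- ad %>%
    dplyr::group_by(.data$raw_text) %>%
    dplyr::summarise(nflag = sum(.data$annotation_flag), .groups = "drop")
  add("ad: one flagged row per string", all(flags$nflag == 1),
      paste0("violations: ",
             paste(flags$raw_text[flags$nflag != 1], collapse = ", ")))

  rst <- mappings$rst
  rcats <- unique(rst$rst_category)
  add("rst: 7 categories", length(rcats) == 7, paste0("found ", length(rcats)))
  add("rst: levels within 1-7 (0 reserved for standby)",
      all(rst$rst_level %in% 1:7), "")
  lvl_by_cat <- rst %>%
    dplyr::distinct(.data$rst_category, .data$rst_level)
  add("rst: one level per category",
      !anyDuplicated(lvl_by_cat$rst_category), "")

  comp <- mappings$compatibility
  pcols <- c("o2_flow_flowmeter", "o2_flow_not_flowmeter", "fio2", "peep",
             "psupp", "pinsp", "set_rate")
  add("compatibility: 7 parameter columns",
      identical(setdiff(names(comp), "rst_level"), pcols),
      paste(names(comp), collapse = ","))
  add("compatibility: levels 1-7", identical(sort(comp$rst_level), 1:7 + 0L) ||
        identical(sort(comp$rst_level), as.numeric(1:7)), "")
  lvl1 <- comp[comp$rst_level == 1, pcols]
  add("compatibility: level-1 row all FALSE",
      nrow(lvl1) == 1 && !any(unlist(lvl1)), "")

  med <- mappings$medication
  add("medication: 8 route categories",
      length(unique(med$route_category)) == 8,
      paste0("found ", length(unique(med$route_category))))
  add("medication: 2 techniques",
      setequal(unique(med$technique), c("bolus", "continuous")), "")
  add("medication: no stop/decrease relevance for SpO2_low",
      !any(med$rel_stop_SpO2_low), "")

  mix <- mappings$mixture
  add("mixture: ingredient sets of size >= 2",
      all(vapply(strsplit(mix$ingredient_set, "+", fixed = TRUE),
                 length, 1L) >= 2), "")
  add("mixture: no stop/decrease relevance for SpO2_low",
      !any(mix$rel_stop_SpO2_low), "")

  dplyr::bind_rows(checks)
}

#' Resolve an airway-device entry to its annotation level
#'
#' Looks a raw documentation string up in the airway-device mapping and
#' returns the level flagged for annotation (free-text entries mapped to
#' several categories carry exactly one flagged row). Entries mapped only to
#' level 0 are documentation artifacts, not airway devices, and are reported
#' as ignorable (`NA` level with status `"ignorable"`); strings absent from
#' the mapping yield status `"unmapped"`, never a silent default.
#'
#' @param entry_text Character vector of raw airway-device strings.
#' @param mappings An `alarm_mappings` object.
#' @return A tibble with columns `entry_text`, `ad_category`, `ad_level`,
#'   `status` (`"mapped"`, `"ignorable"` or `"unmapped"`).
#' @export
#' @examples
#' m <- default_mappings()
#' resolve_ad_level(c("Tubus", "Maske", "???"), m)
resolve_ad_level <- function(entry_text, mappings) {
  flagged <- mappings$ad[mappings$ad$annotation_flag, ]
  idx <- match(entry_text, flagged$raw_text)
  lvl <- flagged$ad_level[idx]
  cat <- flagged$ad_category[idx]
  status <- dplyr::case_when(
    is.na(idx) ~ "unmapped",
    lvl == 0 ~ "ignorable",
    TRUE ~ "mapped"
  )
  lvl[status != "mapped"] <- NA_real_
  cat[status == "unmapped"] <- NA_character_
  tibble::tibble(
    entry_text = entry_text, ad_category = cat,
    ad_level = as.numeric(lvl), status = status
  )
}

#' Resolve a ventilation device/mode pair to its respiratory support therapy
#'
#' Ventilation devices (VD) and modes (VM) are always documented in
#' combination; each combination maps to one respiratory-support-therapy
#' (RST) category and level. In the rare ambiguous cases where one VD-VM
#' pair maps to several categories, the documented airway-device category
#' decides; with no (or a non-deciding) airway device the default row (blank
#' airway-device key) applies.
#'
#' @param vd_text,vm_text Character vectors (recycled to common length).
#' @param ad_category Optional character vector of airway-device categories.
#' @param mappings An `alarm_mappings` object.
#' @return A tibble with columns `vd_text`, `vm_text`, `rst_category`,
#'   `rst_level`, `status` (`"mapped"` or `"unmapped"`).
#' @export
resolve_rst <- function(vd_text, vm_text, ad_category = NULL, mappings) {
  n <- max(length(vd_text), length(vm_text))
  vd <- rep_len(vd_text, n)
  vm <- rep_len(vm_text, n)
  ad <- if (is.null(ad_category)) rep("", n) else rep_len(ad_category, n)
  ad[is.na(ad)] <- ""
  rst <- mappings$rst
  key <- paste(rst$vd_text, rst$vm_text, rst$ad_category, sep = "\r")
  specific <- match(paste(vd, vm, ad, sep = "\r"), key)
  default <- match(paste(vd, vm, "", sep = "\r"), key)
  hit <- ifelse(is.na(specific), default, specific)
  tibble::tibble(
    vd_text = vd, vm_text = vm,
    rst_category = rst$rst_category[hit],
    rst_level = as.numeric(rst$rst_level[hit]),
    status = ifelse(is.na(hit), "unmapped", "mapped")
  )
}

#' Ventilation parameter / therapy compatibility
#'
#' Whether a settable ventilation parameter can be set under a given
#' respiratory-support-therapy level, per the compatibility table. Level 0
#' (standby semantics) is never settable; level 1 (formally not a
#' respiratory support therapy) has an all-`FALSE` row. The logical oxygen
#' flow parameter `"o2_flow"` resolves to the flowmeter column at level 2
#' and to the non-flowmeter column elsewhere; the two physical columns can
#' also be addressed directly.
#'
#' @param rst_level Integer vector of levels 0-7.
#' @param parameter Character vector among [vent_parameters()] or the
#'   explicit columns `"o2_flow_flowmeter"` / `"o2_flow_not_flowmeter"`.
#' @param mappings An `alarm_mappings` object.
#' @return Logical vector.
#' @export
#' @examples
#' m <- default_mappings()
#' is_settable(2, "o2_flow", m)
#' is_settable(5, "pinsp", m)
is_settable <- function(rst_level, parameter, mappings) {
  n <- max(length(rst_level), length(parameter))
  lvl <- rep_len(as.numeric(rst_level), n)
  par <- rep_len(parameter, n)
  if (!all(lvl %in% 0:7)) {
    rlang::abort("rst_level must be within 0-7.")
  }
  col <- ifelse(par == "o2_flow",
                ifelse(lvl == 2, "o2_flow_flowmeter", "o2_flow_not_flowmeter"),
                par)
  known <- c("o2_flow_flowmeter", "o2_flow_not_flowmeter", "fio2", "peep",
             "psupp", "pinsp", "set_rate")
  if (!all(col %in% known)) {
    rlang::abort(paste0("Unknown parameter(s): ",
                        paste(unique(par[!col %in% known]), collapse = ", ")))
  }
  comp <- mappings$compatibility
  out <- logical(n)
  in_table <- lvl %in% comp$rst_level
  row <- match(lvl, comp$rst_level)
  if (any(in_table)) {
    out[in_table] <- mapply(function(r, cc) isTRUE(comp[[cc]][r]),
                            row[in_table], col[in_table])
  }
  out  # level 0 rows stay FALSE
}

#' Medication relevance lookup
#'
#' Decides whether a drug product (by hospital drug id) or an explicit
#' ingredient set is relevant for a given PAC and intervention type. Single
#' ingredients resolve through the medication mapping; products combining
#' two or more active ingredients ("mixtures") resolve through the mixture
#' mapping keyed by the sorted ingredient set. Stop/decrease relevance never
#' exists for the low-saturation condition. Unknown ids or sets yield
#' `FALSE` with status `"unmapped"`.
#'
#' @param drug_id A single drug id, or `NULL` when `ingredient_set` given.
#' @param ingredient_set Character vector of active ingredients (>= 2 treats
#'   the combination as a mixture).
#' @param pac One PAC id.
#' @param intervention_type `"give_or_increase"` or `"stop_or_decrease"`.
#' @param mappings An `alarm_mappings` object.
#' @return A list with `relevant` (logical) and `status` (`"mapped"` or
#'   `"unmapped"`).
#' @export
medication_relevant <- function(drug_id = NULL, ingredient_set = NULL, pac,
                                intervention_type = c("give_or_increase",
                                                      "stop_or_decrease"),
                                mappings) {
  intervention_type <- match.arg(intervention_type)
  stopifnot(pac %in% pac_table()$pac_id)
  col <- paste0(ifelse(intervention_type == "give_or_increase",
                       "rel_give_", "rel_stop_"), pac)
  med <- mappings$medication
  if (is.null(ingredient_set)) {
    rows <- med[med$drug_id == drug_id, , drop = FALSE]
    if (nrow(rows) == 0) {
      return(list(relevant = FALSE, status = "unmapped"))
    }
    ingredient_set <- rows$active_ingredient
    if (length(ingredient_set) == 1) {
      return(list(relevant = isTRUE(rows[[col]][1]), status = "mapped"))
    }
  }
  if (length(ingredient_set) == 1) {
    rows <- med[med$active_ingredient == ingredient_set, , drop = FALSE]
    if (nrow(rows) == 0) return(list(relevant = FALSE, status = "unmapped"))
    return(list(relevant = any(rows[[col]]), status = "mapped"))
  }
  key <- paste(sort(unique(ingredient_set)), collapse = "+")
  mix <- mappings$mixture
  hit <- match(key, mix$ingredient_set)
  if (is.na(hit)) {
    rlang::warn(paste0("Unknown mixture '", key, "'; treated as not relevant."))
    return(list(relevant = FALSE, status = "unmapped"))
  }
  list(relevant = isTRUE(mix[[col]][hit]), status = "mapped")
}
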