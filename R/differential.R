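#' Fold change of a treatment intensity against control
#'
#' Treated/control ratio with explicit sentinels for the boundary
#' cases that Table-style summaries distinguish: a de-novo event
#' (absent in control, present after treatment), a lost event
#' (present in control, absent after), and undefined (absent in
#' both).
#'
#' @param treated,control Non-negative intensity vectors (recycled).
#' @return A tibble with columns `fc` (numeric; NA for sentinels) and
#'   `status` ("ratio", "de_novo", "lost", "undefined").
#' @examples
#' fold_change(190, 100)  # fc 1.9
#' @export
fold_change <- function(treated, control) {
  stopifnot(all(treated >= 0, na.rm = TRUE), all(control >= 0, na.rm = TRUE))
  n <- max(length(treated), length(control))
  treated <- rep_len(treated, n)
  control <- rep_len(control, n)
  status <- dplyr::case_when(
    treated > 0 & control > 0 ~ "ratio",
    treated > 0 & control == 0 ~ "de_novo",
    treated == 0 & control > 0 ~ "lost",
    TRUE ~ "undefined"
  )
  tibble::tibble(
    fc = ifelse(status == "ratio", treated / control, NA_real_),
    status = status
  )
}

# category of one timepoint from intensities (preferred) or a printed
# annotation ("ns", "nd", "at 1 h", or a bare fold-change number)
.categorize_one <- function(treated, control, annotation, up, down) {
  if (!is.na(treated) && !is.na(control)) {
    f <- fold_change(treated, control)
    return(switch(f$status,
      ratio = if (f$fc >= up) "increased" else if (f$fc <= down) "decreased"
              else "unchanged",
      de_novo = "de_novo",
      lost = "lost",
      undefined = "not_detected"
    ))
  }
  if (is.na(annotation)) return("not_detected")
  ann <- tolower(trimws(annotation))
  if (ann == "ns") return("unchanged")
  if (ann == "nd") return("not_detected")
  if (grepl("^at ", ann)) return("de_novo")
  value <- suppressWarnings(as.numeric(ann))
  if (is.na(value)) {
    stop("unrecognized fold-change annotation '", annotation, "'",
         call. = FALSE)
  }
  # a printed fold change is a rounded number: compare it against the
  # thresholds rounded to the same printed precision, so e.g. "0.67"
  # is decreased at the 1/1.5 threshold it was rounded from
  decimals <- nchar(sub("^[0-9]*\\.?", "", ann))
  if (value >= round(up, decimals)) {
    "increased"
  } else if (value <= round(down, decimals)) {
    "decreased"
  } else {
    "unchanged"
  }
}

#' Categorize citrullination changes per timepoint
#'
#' Assigns each record a category at 1 h and 24 h relative to control:
#' `unchanged` (fold change strictly inside (down, up)), `increased` /
#' `decreased` (outside), `de_novo` (absent in control, detected at
#' the timepoint), `lost` (the converse), `not_detected` (absent in
#' both). When intensity columns are missing or NA the printed
#' annotations (`fc_1h`, `fc_24h`: "ns", "nd", "at 1 h"/"at 24 h", or
#' a number) are honoured instead.
#'
#' @param quant A quantification tibble with columns `accession` and
#'   either `intensity_control`/`intensity_1h`/`intensity_24h` or
#'   annotation columns `fc_1h`/`fc_24h`.
#' @param up Upper fold-change threshold (default 1.5).
#' @param down Lower threshold (default 1/1.5).
#' @return The input with `category_1h`, `category_24h`,
#'   `fc_value_1h`, `fc_value_24h` appended.
#' @export
categorize_changes <- function(quant, up = 1.5, down = 1 / 1.5) {
  stopifnot(is.data.frame(quant), up > 1, down < 1, down > 0)
  n <- nrow(quant)
  get_col <- function(name, default) {
    if (name %in% names(quant)) quant[[name]] else rep(default, n)
  }
  ic <- get_col("intensity_control", NA_real_)
  i1 <- get_col("intensity_1h", NA_real_)
  i24 <- get_col("intensity_24h", NA_real_)
  a1 <- as.character(get_col("fc_1h", NA_character_))
  a24 <- as.character(get_col("fc_24h", NA_character_))
  if (any(!is.na(ic) & ic > 0 & is.na(i1) & is.na(a1))) {
    stop("record with control intensity but no 1 h observation or annotation",
         call. = FALSE)
  }
  cat1 <- cat24 <- character(n)
  fc1 <- fc24 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cat1[i] <- .categorize_one(i1[i], ic[i], a1[i], up, down)
    cat24[i] <- .categorize_one(i24[i], ic[i], a24[i], up, down)
    if (!is.na(i1[i]) && !is.na(ic[i]) && ic[i] > 0 && i1[i] > 0) {
      fc1[i] <- i1[i] / ic[i]
    } else if (!is.na(a1[i])) {
      fc1[i] <- suppressWarnings(as.numeric(a1[i]))
    }
    if (!is.na(i24[i]) && !is.na(ic[i]) && ic[i] > 0 && i24[i] > 0) {
      fc24[i] <- i24[i] / ic[i]
    } else if (!is.na(a24[i])) {
      fc24[i] <- suppressWarnings(as.numeric(a24[i]))
    }
  }
  dplyr::mutate(quant, category_1h = cat1, category_24h = cat24,
                fc_value_1h = fc1, fc_value_24h = fc24)
}

#' Summarize citrullination changes into overall classes
#'
#' Collapses per-timepoint categories into one disjoint class per
#' record: `de_novo` (de novo at >= 1 timepoint), `differential`
#' (increased or decreased at >= 1 timepoint, control detected),
#' `lost` (lost at >= 1 timepoint, no differential change), `baseline`
#' (unchanged wherever detected), `not_detected` (never observed).
#'
#' @param categorized Output of [categorize_changes()].
#' @return A `cit_summary` object: tibble `classes` (`accession`,
#'   `class`) and named counts including `control_detected` (distinct
#'   control-detected accessions).
#' @export
summarize_changes <- function(categorized) {
  needed <- c("accession", "category_1h", "category_24h")
  stopifnot(is.data.frame(categorized),
            all(needed %in% names(categorized)))
  cls <- vapply(seq_len(nrow(categorized)), function(i) {
    cats <- c(categorized$category_1h[i], categorized$category_24h[i])
    if (any(cats == "de_novo")) return("de_novo")
    if (any(cats %in% c("increased", "decreased"))) return("differential")
    if (any(cats == "lost")) return("lost")
    if (any(cats == "unchanged")) return("baseline")
    "not_detected"
  }, character(1))
  classes <- tibble::tibble(accession = categorized$accession, class = cls)
  control_detected <- dplyr::n_distinct(
    categorized$accession[cls %in% c("baseline", "differential", "lost")]
  )
  counts <- c(
    baseline = sum(cls == "baseline"),
    differential = sum(cls == "differential"),
    de_novo = sum(cls == "de_novo"),
    lost = sum(cls == "lost"),
    not_detected = sum(cls == "not_detected"),
    control_detected = control_detected
  )
  structure(list(classes = classes, counts = counts),
            class = "cit_summary")
}

#' @export
print.cit_summary <- function(x, ...) {
  cat("<cit_summary>\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-17s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}
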