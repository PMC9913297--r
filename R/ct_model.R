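# Ct data model: ingestion of long-format Ct tables, array-card objects,
# global-mean normalisation, the comparative Ct method, expression tiering
# and self-renewal assay metrics.

#' Construct an array card
#'
#' An array card holds one sample's panel of gene-to-Ct measurements for a
#' single card platform, together with its culture condition and cell line.
#'
#' @param sample_id Sample identifier.
#' @param condition Culture condition, `"2D"` or `"3D"`.
#' @param platform Card platform, one of `"PLURIPOTENCY"`, `"WNT"`, `"ABC"`.
#' @param measurements Data frame with columns `gene` (unique, upper-case
#'   symbols), `ct` (numeric, in (0, 40]), `detected` (logical) and
#'   `is_control` (logical, endogenous-control flag).
#' @param cell_line Optional cell-line label.
#' @return An object of class `ct_card`.
#' @export
ct_card <- function(sample_id, condition, platform, measurements,
                    cell_line = NA_character_) {
  condition <- normalise_condition(condition)
  platform <- toupper(platform)
  stopifnot(is.data.frame(measurements),
            all(c("gene", "ct", "detected", "is_control") %in%
                  names(measurements)))
  if (anyDuplicated(measurements$gene))
    stop("duplicate gene symbols on card ", sample_id, "/", platform, ": ",
         paste(unique(measurements$gene[duplicated(measurements$gene)]),
               collapse = ", "))
  bad <- !is.finite(measurements$ct) | measurements$ct <= 0 |
    measurements$ct > CT_MAX
  if (any(bad))
    stop("Ct values must lie in (0, ", CT_MAX, "]; offending genes: ",
         paste(measurements$gene[bad], collapse = ", "))
  structure(list(sample_id = as.character(sample_id),
                 condition = condition,
                 platform = platform,
                 cell_line = as.character(cell_line),
                 measurements = measurements),
            class = "ct_card")
}

#' @export
print.ct_card <- function(x, ...) {
  cat(sprintf("<ct_card> sample %s [%s, %s]: %d genes (%d detected, %d controls)\n",
              x$sample_id, x$condition, x$platform,
              nrow(x$measurements), sum(x$measurements$detected),
              sum(x$measurements$is_control)))
  invisible(x)
}

normalise_condition <- function(x) {
  key <- toupper(gsub("[^0-9A-Za-z]", "", as.character(x)))
  out <- c("2D" = "2D", "TWOD" = "2D", "3D" = "3D", "THREED" = "3D")[key]
  if (any(is.na(out)))
    stop("unknown condition label: ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected 2D or 3D)")
  unname(out)
}

#' Read a long-format Ct table into array cards
#'
#' Expects a delimited text file with header columns `sample`, `condition`,
#' `platform`, `gene`, `ct` (and optionally `cell_line`). One `ct_card` is
#' produced per (sample, platform) pair. A raw Ct of `"Undetermined"` (or
#' any non-numeric value, or an empty field) is stored as Ct = 40 with
#' `detected = FALSE`; numeric Ct values above 35 are likewise flagged
#' undetected.
#'
#' @param path Path to a CSV/TSV file. The delimiter defaults to tab, or
#'   comma for a `.csv` extension.
#' @param sep Field delimiter override.
#' @param control_genes Endogenous-control symbols to flag; defaults to
#'   [DEFAULT_CONTROL_GENES].
#' @return List of [ct_card] objects.
#' @export
read_ct_table <- function(path, sep = NULL,
                          control_genes = DEFAULT_CONTROL_GENES) {
  if (!file.exists(path)) stop("Ct table not found: ", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  need <- c("sample", "condition", "platform", "gene", "ct")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("Ct table missing required columns: ", paste(missing, collapse = ", "))
  raw$gene <- toupper(trimws(raw$gene))
  raw$platform <- toupper(trimws(raw$platform))
  raw$condition <- normalise_condition(raw$condition)
  key <- paste(raw$sample, raw$platform, raw$gene, sep = "|")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (sample, platform, gene) entry: ", gsub("\\|", ", ", d))
  }
  ct_num <- suppressWarnings(as.numeric(raw$ct))
  undet <- !is.finite(ct_num)
  ct_num[undet] <- CT_MAX
  detected <- !undet & ct_num <= CT_DETECT
  raw$.ct <- ct_num
  raw$.detected <- detected
  cards <- lapply(split(raw, paste(raw$sample, raw$platform, sep = "|")),
                  function(df) {
    ct_card(sample_id = df$sample[1],
            condition = df$condition[1],
            platform = df$platform[1],
            cell_line = if ("cell_line" %in% names(df)) df$cell_line[1]
                        else NA_character_,
            measurements = data.frame(
              gene = df$gene,
              ct = df$.ct,
              detected = df$.detected,
              is_control = df$gene %in% toupper(control_genes),
              stringsAsFactors = FALSE))
  })
  unname(cards[order(vapply(cards, function(cc)
    paste(cc$sample_id, cc$platform), ""))])
}

#' Global-mean normalisation of one card
#'
#' Subtracts the card's global mean Ct (over the analysis panel) from each
#' panel gene, yielding a delta-Ct vector that sums to zero over the panel.
#' By default the panel is every non-control gene on the card, including
#' undetected genes held at Ct = 40; `detected_only = TRUE` restricts the
#' mean (but not the reported genes) to detected panel genes.
#'
#' @param card A [ct_card].
#' @param panel Optional character vector of panel genes; must be a subset
#'   of the card's genes and exclude endogenous controls.
#' @param detected_only Compute the global mean over detected panel genes
#'   only.
#' @return Object of class `delta_ct`: list with `sample_id` and `values`,
#'   a named numeric vector of delta-Ct values (cycles).
#' @export
global_mean_normalise <- function(card, panel = NULL, detected_only = FALSE) {
  stopifnot(inherits(card, "ct_card"))
  m <- card$measurements
  if (is.null(panel)) panel <- m$gene[!m$is_control]
  panel <- toupper(panel)
  if (!length(panel)) stop("normalisation panel is empty")
  absent <- setdiff(panel, m$gene)
  if (length(absent))
    stop("panel genes absent from card ", card$sample_id, ": ",
         paste(absent, collapse = ", "))
  ctrl <- intersect(panel, m$gene[m$is_control])
  if (length(ctrl))
    stop("panel must exclude endogenous controls: ",
         paste(ctrl, collapse = ", "))
  ct <- setNames(m$ct, m$gene)[panel]
  det <- setNames(m$detected, m$gene)[panel]
  base <- if (detected_only) {
    if (!any(det)) stop("no detected panel genes on card ", card$sample_id)
    mean(ct[det])
  } else mean(ct)
  structure(list(sample_id = card$sample_id, values = ct - base),
            class = "delta_ct")
}

#' Build a delta-Ct matrix from a set of array cards
#'
#' Groups cards by sample and normalises against the global mean, either
#' jointly across all of a sample's card platforms (`scope = "joint"`, the
#' default, allowing direct comparison across platforms) or per card
#' (`scope = "per_card"`). Endogenous controls are excluded from the panel.
#'
#' @param cards List of [ct_card] objects.
#' @param scope `"joint"` or `"per_card"` global mean.
#' @param detected_only Passed to the global-mean computation.
#' @return Object of class `dct_matrix`: list with `dct` (genes x samples
#'   delta-Ct matrix), `ct` (raw Ct matrix), `detected` (logical matrix)
#'   and `samples` (data frame sample_id, condition, cell_line).
#' @export
build_dct_matrix <- function(cards, scope = c("joint", "per_card"),
                             detected_only = FALSE) {
  scope <- match.arg(scope)
  stopifnot(length(cards) > 0, all(vapply(cards, inherits, TRUE, "ct_card")))
  by_sample <- split(cards, vapply(cards, function(x) x$sample_id, ""))
  genes <- sort(unique(unlist(lapply(cards, function(x)
    x$measurements$gene[!x$measurements$is_control]))))
  cols <- lapply(by_sample, function(cs) {
    meas <- do.call(rbind, lapply(cs, function(x)
      x$measurements[!x$measurements$is_control, , drop = FALSE]))
    if (anyDuplicated(meas$gene))
      stop("gene measured on more than one platform for sample ",
           cs[[1]]$sample_id, ": ",
           paste(unique(meas$gene[duplicated(meas$gene)]), collapse = ", "))
    if (!setequal(meas$gene, genes))
      stop("sample ", cs[[1]]$sample_id,
           " does not cover the common gene panel")
    if (scope == "joint") {
      pooled <- ct_card(cs[[1]]$sample_id, cs[[1]]$condition, "PLURIPOTENCY",
                        meas, cs[[1]]$cell_line)
      dct <- global_mean_normalise(pooled, detected_only = detected_only)$values
    } else {
      dct <- unlist(lapply(cs, function(x)
        global_mean_normalise(x, detected_only = detected_only)$values))
    }
    list(dct = dct[genes],
         ct = setNames(meas$ct, meas$gene)[genes],
         detected = setNames(meas$detected, meas$gene)[genes],
         condition = cs[[1]]$condition,
         cell_line = cs[[1]]$cell_line)
  })
  structure(list(
    dct = vapply(cols, `[[`, numeric(length(genes)), "dct"),
    ct = vapply(cols, `[[`, numeric(length(genes)), "ct"),
    detected = vapply(cols, `[[`, logical(length(genes)), "detected"),
    samples = data.frame(sample_id = names(cols),
                         condition = vapply(cols, `[[`, "", "condition"),
                         cell_line = vapply(cols, `[[`, "", "cell_line"),
                         stringsAsFactors = FALSE, row.names = NULL)),
    class = "dct_matrix")
}

#' Comparative Ct fold change
#'
#' Computes the fold change `2^-ddCt` where
#' `ddCt = (Ct_target_sample - Ct_reference_sample) -
#'         (Ct_target_calibrator - Ct_reference_calibrator)`.
#' A ddCt of one cycle corresponds to a halving of expression relative to
#' the calibrator; negative ddCt to an increase.
#'
#' @param ct_target_sample,ct_ref_sample Target and reference-gene Ct in
#'   the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Target and reference-gene
#'   Ct in the calibrator sample.
#' @return Fold change (numeric, vectorised).
#' @export
comparative_ct <- function(ct_target_sample, ct_ref_sample,
                           ct_target_calibrator, ct_ref_calibrator) {
  args <- list(ct_target_sample, ct_ref_sample,
               ct_target_calibrator, ct_ref_calibrator)
  if (!all(vapply(args, function(x) all(is.finite(x)), TRUE)))
    stop("all four Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Expression tier of a Ct value
#'
#' Partitions the Ct axis into `HIGH` (Ct < 25), `EXPRESSED`
#' (25 <= Ct <= 35) and `NOT_DETECTED` (Ct > 35). The boundaries 25 and 35
#' fall in the `EXPRESSED` tier so the partition is exhaustive.
#'
#' @param ct Numeric Ct values in (0, 40].
#' @return Factor with levels `HIGH`, `EXPRESSED`, `NOT_DETECTED`.
#' @export
classify_tier <- function(ct) {
  if (!all(is.finite(ct) & ct > 0 & ct <= CT_MAX))
    stop("Ct values must lie in (0, ", CT_MAX, "]")
  tier <- ifelse(ct < CT_HIGH, "HIGH",
                 ifelse(ct <= CT_DETECT, "EXPRESSED", "NOT_DETECTED"))
  factor(tier, levels = TIER_LEVELS)
}

TIER_LEVELS <- c("HIGH", "EXPRESSED", "NOT_DETECTED")

#' Spheroid forming efficiency
#'
#' Percentage of single-cell-seeded wells that produced a spheroid:
#' `100 * wells_with_progeny / wells_seeded`.
#'
#' @param wells_with_progeny Number of wells containing a spheroid.
#' @param wells_seeded Number of wells seeded with a single cell (> 0).
#' @return Percentage.
#' @export
spheroid_forming_efficiency <- function(wells_with_progeny, wells_seeded) {
  stopifnot(wells_with_progeny >= 0, wells_seeded >= 0,
            wells_with_progeny <= wells_seeded)
  if (any(wells_seeded == 0)) stop("wells_seeded must be positive")
  100 * wells_with_progeny / wells_seeded
}

#' Colony forming efficiency
#'
#' Percentage of seeded cells that formed a colony in the field of view:
#' `100 * colonies / cells_seeded`.
#'
#' @param colonies Number of colonies counted.
#' @param cells_seeded Number of cells seeded (> 0).
#' @return Percentage.
#' @export
colony_forming_efficiency <- function(colonies, cells_seeded) {
  stopifnot(colonies >= 0, cells_seeded >= 0)
  if (any(cells_seeded == 0)) stop("cells_seeded must be positive")
  100 * colonies / cells_seeded
}

#' Write a delta-Ct matrix to TSV
#'
#' @param x A `dct_matrix` object.
#' @param path Output path (genes x samples TSV with a `gene` column).
#' @export
write_dct_matrix <- function(x, path) {
  stopifnot(inherits(x, "dct_matrix"))
  df <- data.frame(gene = rownames(x$dct), x$dct, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
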