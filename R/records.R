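record_columns <- c(
  "embryo_id", "cell_id", "stage", "volume", "total_area",
  "exposed_area", "junctional_area", "contact_area",
  "prop_exposed", "prop_junctional", "prop_contact",
  "sphericity", "oblateness", "prolateness", "aj_ratio",
  "nc_yap", "ab_perm", "manual_label", "dividing", "compaction_class",
  "qc_flags")

#' Quantify one embryo into per-cell records
#'
#' Runs the full geometry and intensity pipeline on one labelled embryo:
#' surface extraction, domain classification, shape and position
#' descriptors, compartment masks and the N/C YAP and A/B pERM ratios.
#'
#' @param embryo a `labelled_embryo`.
#' @param params a [domain_params()].
#' @param shell intensity shell thickness in µm (default 1).
#' @param smooth_sigma mesh pre-smoothing sd in voxels (default 0.8).
#' @return data.frame with one row per quantified cell (blastomere record).
#' @export
quantify_embryo <- function(embryo, params = domain_params(), shell = 1.0,
                            smooth_sigma = 0.8) {
  surfaces <- extract_surfaces(embryo, smooth_sigma = smooth_sigma)
  dmap <- classify_domains(surfaces, embryo, params)
  shp <- shape_descriptors(embryo, surfaces)
  pos <- position_descriptors(dmap)
  masks <- compartment_masks(embryo, shell = shell, delta = params$delta)

  nc <- if (!is.null(embryo$channels$yap)) {
    nc_ratio(embryo$channels$yap, masks)
  } else {
    data.frame(cell_id = shp$cell_id, nc_ratio = NA_real_, flag = "no_channel")
  }
  ab <- if (!is.null(embryo$channels$perm)) {
    ab_ratio(embryo$channels$perm, masks)
  } else {
    data.frame(cell_id = shp$cell_id, ab_ratio = NA_real_, flag = "no_channel")
  }

  df <- merge(shp, pos, by = "cell_id")
  df <- merge(df, stats::setNames(nc, c("cell_id", "nc_yap", "nc_flag")),
              by = "cell_id", all.x = TRUE)
  df <- merge(df, stats::setNames(ab, c("cell_id", "ab_perm", "ab_flag")),
              by = "cell_id", all.x = TRUE)
  n_cells <- max(embryo$cell_labels)
  df$embryo_id <- embryo$embryo_id %||% "embryo"
  df$stage <- n_cells
  df$manual_label <- "none"
  df$dividing <- FALSE
  df$compaction_class <- "none"
  flags <- paste(ifelse(df$degenerate, "degenerate", ""), df$nc_flag,
                 df$ab_flag, sep = ";")
  df$qc_flags <- gsub("^;+|;+$", "", gsub(";{2,}", ";", flags))
  df[, record_columns]
}

#' Build the pooled blastomere record table
#'
#' Quantifies a list of embryos and merges optional per-cell annotations
#' (manual TE/ICM labels, dividing flags, compaction class). Dividing cells
#' are excluded from the returned table — their geometry differs widely from
#' interphase cells and their nuclear envelope is disassembled — and the
#' number dropped is reported in a message.
#'
#' @param embryos a `labelled_embryo` or list of them.
#' @param annotations optional data.frame keyed by (`embryo_id`, `cell_id`)
#'   with any of `manual_label` (TE / ICM / none), `dividing` (logical),
#'   `compaction_class` (pre / compacting / post / none). Rows referencing
#'   unknown cells are an error listing the offenders.
#' @param params,shell,smooth_sigma passed to [quantify_embryo()].
#' @return data.frame of blastomere records, one row per non-dividing cell.
#' @export
build_records <- function(embryos, annotations = NULL,
                          params = domain_params(), shell = 1.0,
                          smooth_sigma = 0.8) {
  if (inherits(embryos, "labelled_embryo")) embryos <- list(embryos)
  recs <- do.call(rbind, lapply(embryos, quantify_embryo, params = params,
                                shell = shell, smooth_sigma = smooth_sigma))
  rownames(recs) <- NULL

  if (!is.null(annotations)) {
    stopifnot(all(c("embryo_id", "cell_id") %in% names(annotations)))
    key_rec <- paste(recs$embryo_id, recs$cell_id)
    key_ann <- paste(annotations$embryo_id, annotations$cell_id)
    unknown <- !(key_ann %in% key_rec)
    if (any(unknown)) {
      stop("annotations reference unknown cells: ",
           paste(key_ann[unknown], collapse = ", "))
    }
    m <- match(key_rec, key_ann)
    for (col in intersect(c("manual_label", "dividing", "compaction_class"),
                          names(annotations))) {
      hit <- !is.na(m)
      recs[[col]][hit] <- annotations[[col]][m[hit]]
    }
  }

  n_div <- sum(recs$dividing)
  if (n_div > 0) {
    message(sprintf("excluding %d dividing cell(s) from the record table",
                    n_div))
    recs <- recs[!recs$dividing, , drop = FALSE]
    rownames(recs) <- NULL
  }
  recs
}
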