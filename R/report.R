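# Five-comparison simple-design report, helical-wheel geometry, and batch
# R_H--H_Y profiling tables.

#' Helical-wheel projection of a segment
#'
#' Standard alpha-helix wheel: consecutive residues are placed 100 degrees
#' apart on the unit circle (3.6 residues per turn), so residue i sits at
#' `((i - 1) * 100) mod 360` degrees; residue 19 completes five full turns
#' and returns to 0.
#'
#' @param segment_sequence Non-empty segment string.
#' @param changed_positions Positions (1-based within the segment) to flag.
#' @return Data frame of class `qty_wheel`: `index`, `residue`, `angle`
#'   (degrees), `x`, `y` (unit circle), `changed`.
#' @export
helical_wheel <- function(segment_sequence, changed_positions = integer(0)) {
  s <- seq_chars(as_sequence(segment_sequence))
  idx <- seq_along(s)
  angle <- ((idx - 1) * 100) %% 360
  structure(
    data.frame(index = idx, residue = s, angle = angle,
               x = cospi(angle / 180), y = sinpi(angle / 180),
               changed = idx %in% as.integer(changed_positions),
               stringsAsFactors = FALSE),
    class = c("qty_wheel", "data.frame")
  )
}

#' Render a wheel projection as a minimal SVG drawing
#'
#' @param wheel A `qty_wheel`.
#' @param path Output path.
#' @param size Canvas size in px.
#' @return `path`, invisibly.
#' @export
write_wheel_svg <- function(wheel, path, size = 300) {
  r <- size * 0.4; cx <- size / 2; cy <- size / 2
  px <- cx + r * wheel$x; py <- cy - r * wheel$y
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">', size, size),
    sprintf('<circle cx="%g" cy="%g" r="%g" fill="none" stroke="grey"/>', cx, cy, r),
    sprintf('<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="lightgrey"/>', cx, cy, px, py),
    sprintf('<circle cx="%g" cy="%g" r="9" fill="%s" stroke="black"/>',
            px, py, ifelse(wheel$changed, "tomato", "white")),
    sprintf('<text x="%g" y="%g" font-size="9" text-anchor="middle" dy="3">%s%d</text>',
            px, py, wheel$residue, wheel$index),
    '</svg>'
  )
  writeLines(lines, path)
  invisible(path)
}

#' Five-comparison simple-design report
#'
#' Assembles the standard report of a simple (full-substitution) design:
#' (1) general characteristics (MW, pI, H_Y for WT and variant),
#' (2) TM-region comparison (input topology vs the topologies the fallback
#' caller finds in WT and variant), (3) per-helix comparison (helix
#' propensity and SS3 slices per TM), (4) TM sequence alignments, and
#' (5) helical wheels per TM. All numeric cells are taken from the property
#' and design functions -- the report never recomputes anything its own way.
#' When no external SS3 pair is supplied the secondary-structure cells fall
#' back to [fallback_ss3()] and are labeled `"fallback-estimated"`.
#'
#' @param record `qty_record` of the WT protein.
#' @param design `qty_design` of the variant.
#' @param ss3_pair Optional list with `wt` and `mt` SS3 strings from an
#'   external predictor.
#' @param config `qty_predictor_config`.
#' @return List of class `qty_report` with elements `meta` and `sections`
#'   (exactly five).
#' @export
simple_design_report <- function(record, design, ss3_pair = NULL,
                                 config = predictor_config()) {
  if (record$sequence != design$wt_sequence)
    qty_stop("design does not belong to this record", "qty_input_error")
  ss3_source <- if (is.null(ss3_pair)) "fallback-estimated" else "external"
  if (is.null(ss3_pair)) {
    ss3_pair <- list(wt = fallback_ss3(design$wt_sequence, config),
                     mt = fallback_ss3(design$mt_sequence, config))
  } else {
    ss3_pair$wt <- validate_ss3(ss3_pair$wt, nchar(design$wt_sequence))
    ss3_pair$mt <- validate_ss3(ss3_pair$mt, nchar(design$mt_sequence))
  }
  prof_wt <- property_profile(design$wt_sequence, ss3 = ss3_pair$wt)
  prof_mt <- property_profile(design$mt_sequence, ss3 = ss3_pair$mt)
  general <- data.frame(
    sequence = c("WT", design$code_name),
    mw_kda = round(c(prof_wt$mw_kda, prof_mt$mw_kda), 2),
    pi = round(c(prof_wt$pi, prof_mt$pi), 2),
    hy = round(c(prof_wt$hy, prof_mt$hy), 4),
    rh = round(c(prof_wt$rh, prof_mt$rh), 4),
    tm_index = round(c(prof_wt$tm_index, prof_mt$tm_index), 4),
    stringsAsFactors = FALSE
  )
  topo_wt <- predict_tm_fallback(design$wt_sequence, config)
  topo_mt <- predict_tm_fallback(design$mt_sequence, config)
  tm_regions <- list(
    input = as.data.frame(design$topology),
    wt_predicted = as.data.frame(topo_wt),
    mt_predicted = as.data.frame(topo_mt)
  )
  per_helix <- do.call(rbind, lapply(seq_len(nrow(design$topology)), function(i) {
    a <- design$topology$start[i]; b <- design$topology$end[i]
    wt_seg <- substr(design$wt_sequence, a, b)
    mt_seg <- substr(design$mt_sequence, a, b)
    data.frame(
      label = design$topology$label[i],
      n_changes = unname(design$per_segment_changes[i]),
      helix_propensity_wt = round(helix_propensity(wt_seg), 4),
      helix_propensity_mt = round(helix_propensity(mt_seg), 4),
      ss3_wt = substr(ss3_pair$wt, a, b),
      ss3_mt = substr(ss3_pair$mt, a, b),
      soluble_mt = is_soluble_segment(mt_seg, config),
      stringsAsFactors = FALSE
    )
  }))
  alignments <- lapply(seq_len(nrow(design$topology)), function(i) {
    a <- design$topology$start[i]; b <- design$topology$end[i]
    d <- diff_alignment(design)
    d[d$position >= a & d$position <= b, c("position", "wt", "mt", "changed")]
  })
  names(alignments) <- design$topology$label
  wheels <- lapply(seq_len(nrow(design$topology)), function(i) {
    a <- design$topology$start[i]; b <- design$topology$end[i]
    ch <- design$changed_positions
    helical_wheel(substr(design$mt_sequence, a, b), ch[ch >= a & ch <= b] - a + 1L)
  })
  names(wheels) <- design$topology$label
  structure(list(
    meta = list(
      id = record$id,
      code = design$code_name,
      masked = design$masked,
      r_act = round(r_act(design), 4),
      r_sc = round(r_sc(ss3_pair$wt, ss3_pair$mt), 4),
      ss3_source = ss3_source
    ),
    sections = list(
      general_characteristics = general,
      tm_regions = tm_regions,
      per_helix = per_helix,
      alignments = alignments,
      wheels = wheels
    )
  ), class = "qty_report")
}

#' Serialize a report to JSON
#'
#' Deterministic for identical inputs: parsing the output and re-serializing
#' it reproduces the same bytes.
#'
#' @param report A `qty_report` (or a plain list parsed back from JSON).
#' @return JSON string.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = 8, pretty = TRUE, dataframe = "columns"))
}

#' Render a report as plain text
#' @param report A `qty_report`.
#' @return Character vector of lines.
#' @export
report_text <- function(report) {
  out <- c(
    sprintf("QTY simple design report - %s (%s code)", report$meta$id, report$meta$code),
    sprintf("R_ACT %.4f | R_SC %.4f (%s)", report$meta$r_act, report$meta$r_sc,
            report$meta$ss3_source),
    "", "[1] General characteristics")
  g <- report$sections$general_characteristics
  out <- c(out, utils::capture.output(print(g, row.names = FALSE)))
  out <- c(out, "", "[2] TM regions (input / WT predicted / MT predicted)")
  for (nm in names(report$sections$tm_regions)) {
    t <- report$sections$tm_regions[[nm]]
    out <- c(out, sprintf("  %s: %s", nm,
                          if (nrow(t) == 0) "(none)" else
                            paste(sprintf("%d-%d", t$start, t$end), collapse = ", ")))
  }
  out <- c(out, "", "[3] Per-helix comparison",
           utils::capture.output(print(report$sections$per_helix, row.names = FALSE)))
  out <- c(out, "", "[4] TM alignments (changed positions flagged *)")
  for (nm in names(report$sections$alignments)) {
    a <- report$sections$alignments[[nm]]
    out <- c(out, sprintf("  %s  wt %s", nm, paste(a$wt, collapse = "")),
             sprintf("  %s  mt %s", strrep(" ", nchar(nm)), paste(a$mt, collapse = "")),
             sprintf("  %s     %s", strrep(" ", nchar(nm)),
                     paste(ifelse(a$changed, "*", " "), collapse = "")))
  }
  out <- c(out, "", "[5] Helical wheels: angles at 100 deg/residue",
           vapply(names(report$sections$wheels), function(nm) {
             w <- report$sections$wheels[[nm]]
             sprintf("  %s: %d residues, %d changed", nm, nrow(w), sum(w$changed))
           }, ""))
  out
}

#' @export
print.qty_report <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Batch R_H--H_Y profile of records and their designs
#'
#' One row per protein with WT and variant MW, pI, H_Y, R_H (from the
#' fallback SS3 estimate), Tm index and R_ACT -- the table behind
#' WT-vs-variant hydropathy/helix-ratio scatter maps. Per-record failures
#' are logged and skipped; the returned table carries a `summary` attribute
#' with `n_ok` / `n_failed`.
#'
#' @param records List of `qty_record`.
#' @param topologies List of `qty_topology`, one per record.
#' @param code `qty_code`.
#' @param config `qty_predictor_config`.
#' @return Data frame, one row per successful design.
#' @export
batch_profile <- function(records, topologies, code = qty_code(),
                          config = predictor_config()) {
  stopifnot(length(records) == length(topologies))
  rows <- list(); failures <- character(0)
  for (i in seq_along(records)) {
    res <- tryCatch({
      rec <- records[[i]]
      design <- qty_substitute(rec, topologies[[i]], code)
      ss3_wt <- fallback_ss3(design$wt_sequence, config)
      ss3_mt <- fallback_ss3(design$mt_sequence, config)
      data.frame(
        id = rec$id,
        mw_wt = molecular_weight(design$wt_sequence),
        pi_wt = isoelectric_point(design$wt_sequence),
        hy_wt = hydropathy(design$wt_sequence),
        mw_mt = molecular_weight(design$mt_sequence),
        pi_mt = isoelectric_point(design$mt_sequence),
        hy_mt = hydropathy(design$mt_sequence),
        r_act = r_act(design),
        rh_wt = helix_ratio(ss3_wt),
        rh_mt = helix_ratio(ss3_mt),
        tm_index_wt = tm_index(design$wt_sequence),
        tm_index_mt = tm_index(design$mt_sequence),
        stringsAsFactors = FALSE
      )
    }, qty_error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", records[[i]]$id, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(id = character(0))
  attr(out, "summary") <- list(n_ok = length(rows), n_failed = length(failures),
                               failures = failures)
  out
}
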