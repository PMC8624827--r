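# Ortholog/paralog event classification from lineage-chart dynamics.

#' Classify homologous events along a lineage chart
#'
#' Scans adjacent chart points in order of increasing threshold. Whenever
#' the gene count drops between two adjacent points a homologous event is
#' recorded for that HI interval: if the species count also drops the
#' diverging genes came from other species and the event is
#' **orthologous** (a speciation-era divergence); if the species count is
#' unchanged the diverging genes were extra copies within already-present
#' species and the event is **paralogous** (a duplication-era divergence).
#' An event is *major* when the departing genes are at least `majorFrac`
#' of the lower-threshold group (the group splitting into substantial
#' parts) and *minor* otherwise (a few genes peeling off). Orthologous
#' events whose departing set also contained extra copies of species that
#' stayed are flagged in the `caveat` column as `mixed`.
#'
#' @param chart A [LineageChart-class].
#' @param map Species map `data.frame` (`gene_id`, `species_id`, optional
#'   `family_id`).
#' @param majorFrac Fraction of the group that must depart for an event to
#'   be called major (default 0.25).
#' @return `data.frame` with one row per event: `t_low`, `t_high`, `kind`
#'   (`orthologous`/`paralogous`), `delta_genes`, `delta_species`,
#'   `magnitude` (`major`/`minor`), `caveat`.
#' @export
classifyEvents <- function(chart, map, majorFrac = 0.25) {
  stopifnot(methods::is(chart, "LineageChart"))
  methods::validObject(chart)
  cn <- chartPoints(chart)
  mem <- chartMembers(chart)
  k <- nrow(cn)
  rows <- list()
  if (k >= 2) for (i in seq_len(k - 1)) {
    dg <- cn$n_genes[i] - cn$n_genes[i + 1]
    if (dg <= 0) next
    ds <- cn$n_species[i] - cn$n_species[i + 1]
    kind <- if (ds >= 1) "orthologous" else "paralogous"
    departing <- setdiff(mem[[i]], mem[[i + 1]])
    caveat <- ""
    if (kind == "orthologous") {
      depSp <- unique(map$species_id[match(departing, map$gene_id)])
      staySp <- unique(map$species_id[match(mem[[i + 1]], map$gene_id)])
      if (length(intersect(depSp, staySp))) caveat <- "mixed"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      t_low = cn$threshold[i], t_high = cn$threshold[i + 1],
      kind = kind, delta_genes = dg, delta_species = ds,
      magnitude = if (dg >= majorFrac * cn$n_genes[i]) "major" else "minor",
      caveat = caveat, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(t_low = numeric(0), t_high = numeric(0),
                      kind = character(0), delta_genes = integer(0),
                      delta_species = integer(0), magnitude = character(0),
                      caveat = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genome-level vs localized duplication signature for one species
#'
#' Paralogous events co-occurring in many genes of a species across the
#' same HI interval point to whole- or partial-genome duplication, while
#' isolated paralogous events point to localized duplication (e.g.
#' transposition). For each elementary HI interval between event
#' boundaries, this reports the fraction of the species' charted genes
#' whose lineage shows a paralogous event covering that interval, flagging
#' intervals whose fraction reaches `flagFrac`.
#'
#' @param charts List of [LineageChart-class] objects computed on the same
#'   HI graph (one per focal gene).
#' @param species Species ID of interest.
#' @param map Species map `data.frame`.
#' @param flagFrac Fraction of genes required to flag an interval as a
#'   genome-level duplication candidate (default 0.5).
#' @return `data.frame` with `t_low`, `t_high`, `fraction`, `flagged` for
#'   every elementary interval covered by at least one paralogous event.
#' @export
duplicationSignature <- function(charts, species, map, flagFrac = 0.5) {
  focals <- vapply(charts, focalGene, "")
  sp <- map$species_id[match(focals, map$gene_id)]
  mine <- which(sp == species)
  if (!length(mine))
    stop("no chart has a focal gene from species: ", species)
  evs <- lapply(charts[mine], function(ch) {
    ev <- classifyEvents(ch, map)
    ev[ev$kind == "paralogous", c("t_low", "t_high"), drop = FALSE]
  })
  allIv <- do.call(rbind, evs)
  if (is.null(allIv) || !nrow(allIv))
    return(data.frame(t_low = numeric(0), t_high = numeric(0),
                      fraction = numeric(0), flagged = logical(0)))
  bounds <- sort(unique(c(allIv$t_low, allIv$t_high)))
  lo <- bounds[-length(bounds)]; hi <- bounds[-1]
  frac <- vapply(seq_along(lo), function(j) {
    covered <- vapply(evs, function(iv) {
      any(iv$t_low <= lo[j] & iv$t_high >= hi[j])
    }, logical(1))
    mean(covered)
  }, numeric(1))
  keep <- frac > 0
  data.frame(t_low = lo[keep], t_high = hi[keep], fraction = frac[keep],
             flagged = frac[keep] >= flagFrac)
}

#' Write an event table as TSV
#'
#' @param events Event `data.frame` from [classifyEvents()].
#' @param path Output path.
#' @param header Optional comment lines (written with leading `#`).
#' @export
writeEventTable <- function(events, path, header = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  df <- events
  for (cl in c("t_low", "t_high"))
    df[[cl]] <- format(df[[cl]], digits = 17, trim = TRUE,
                       scientific = FALSE)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' Read an event table written by [writeEventTable()]
#'
#' @param path Input path.
#' @return Event `data.frame`.
#' @export
readEventTable <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$caveat[is.na(df$caveat)] <- ""
  df
}
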