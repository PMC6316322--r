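# Systematic reduction of clustered grove records: one point per grove,
# one record per raster cell, clipped to the modelling extent.

#' Read grove occurrence records from CSV
#'
#' Expected columns: `grove_id, lon, lat[, occupied]`. Sites are kept whether
#' or not they currently support overwintering clusters; when the `occupied`
#' column is absent every record is flagged occupied.
#'
#' @param path CSV path (UTF-8, "." decimal separator).
#' @return A data.frame with columns `grove_id` (character), `lon`, `lat`
#'   (numeric), `occupied` (logical).
#' @export
read_occurrences <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("grove_id", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("occurrence CSV missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    warning("occurrence file has a header but no records: ", path)
    return(data.frame(grove_id = character(0), lon = numeric(0),
                      lat = numeric(0), occupied = logical(0)))
  }
  for (cc in c("lon", "lat")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop(sprintf("non-numeric %s at row(s): %s", cc, paste(bad, collapse = ", ")))
    df[[cc]] <- v
  }
  occupied <- if ("occupied" %in% names(df)) as.logical(df$occupied) else rep(TRUE, nrow(df))
  data.frame(grove_id = as.character(df$grove_id), lon = df$lon, lat = df$lat,
             occupied = occupied, stringsAsFactors = FALSE)
}

#' Write occurrence records to CSV
#' @param records Occurrence data.frame (`grove_id, lon, lat, occupied`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_occurrences <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

new_occurrence_set <- function(records, provenance) {
  structure(list(records = records, provenance = provenance),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<occurrence_set> %d records (from %d raw; %d groves; %d cell duplicates dropped; %d out of extent)\n",
              nrow(x$records), p$n_raw, p$n_groves, p$n_cell_dupes_dropped,
              p$n_out_of_extent))
  invisible(x)
}

#' Collapse clustered records to one point per grove
#'
#' Overwintering records cluster within groves; the modelling unit is the
#' grove, represented by a single point at the centroid of its records. The
#' occupied flag of a grove is the logical OR of its records' flags.
#'
#' @param records Occurrence data.frame (`grove_id, lon, lat, occupied`).
#' @return An `occurrence_set`: `$records` (one row per grove, sorted by
#'   `grove_id`) and `$provenance` counts. Idempotent.
#' @export
collapse_to_groves <- function(records) {
  if (inherits(records, "occurrence_set")) records <- records$records
  if (nrow(records) == 0)
    return(new_occurrence_set(records,
      list(n_raw = 0L, n_groves = 0L, n_cell_dupes_dropped = 0L,
           n_out_of_extent = 0L)))
  if (any(is.na(records$grove_id) | !nzchar(records$grove_id)))
    stop("every record must carry a grove_id")
  agg <- aggregate(records[c("lon", "lat")], by = list(grove_id = records$grove_id), mean)
  occ <- aggregate(list(occupied = records$occupied),
                   by = list(grove_id = records$grove_id), any)
  out <- merge(agg, occ, by = "grove_id")
  out <- out[order(out$grove_id), c("grove_id", "lon", "lat", "occupied")]
  rownames(out) <- NULL
  new_occurrence_set(out, list(n_raw = nrow(records), n_groves = nrow(out),
                               n_cell_dupes_dropped = 0L, n_out_of_extent = 0L))
}

#' Thin grove records to one per raster cell
#'
#' Multiple grove centers within one raster cell contribute no independent
#' information to a cell-based model and inflate spatial autocorrelation;
#' the record with the lexicographically smallest `grove_id` in each cell is
#' retained (deterministic tie-break).
#'
#' @param occ An `occurrence_set` (or plain records data.frame).
#' @param grid A [gn_grid] defining the cell lattice.
#' @return A thinned `occurrence_set`; provenance counts the drops.
#' @export
dedupe_per_cell <- function(occ, grid) {
  prov <- if (inherits(occ, "occurrence_set")) occ$provenance else
    list(n_raw = nrow(occ), n_groves = nrow(occ), n_cell_dupes_dropped = 0L,
         n_out_of_extent = 0L)
  rec <- if (inherits(occ, "occurrence_set")) occ$records else occ
  if (nrow(rec) == 0) return(new_occurrence_set(rec, prov))
  rec <- rec[order(rec$grove_id), , drop = FALSE]
  idx <- cell_index(grid, rec$lon, rec$lat)
  keep <- !duplicated(idx$cell, incomparables = NA)
  dropped <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  prov$n_cell_dupes_dropped <- prov$n_cell_dupes_dropped + dropped
  new_occurrence_set(rec, prov)
}

#' Clip occurrences to a stack's extent and valid mask
#'
#' Records outside the stack's extent, or falling on cells that are nodata in
#' any layer, are dropped and counted in provenance.
#'
#' @param occ An `occurrence_set` (or plain records data.frame).
#' @param stack A [gn_stack].
#' @return A clipped `occurrence_set`.
#' @export
clip_to_extent <- function(occ, stack) {
  prov <- if (inherits(occ, "occurrence_set")) occ$provenance else
    list(n_raw = nrow(occ), n_groves = nrow(occ), n_cell_dupes_dropped = 0L,
         n_out_of_extent = 0L)
  rec <- if (inherits(occ, "occurrence_set")) occ$records else occ
  if (nrow(rec) == 0) return(new_occurrence_set(rec, prov))
  g <- stack$layers[[1]]
  idx <- cell_index(g, rec$lon, rec$lat)
  inside <- !is.na(idx$cell)
  valid <- inside
  valid[inside] <- stack$mask[cbind(idx$row[inside], idx$col[inside])]
  n_drop <- sum(!valid)
  if (n_drop > 0)
    log_msg(sprintf("clip_to_extent: dropped %d record(s) outside extent or on nodata cells", n_drop))
  rec <- rec[valid, , drop = FALSE]
  rownames(rec) <- NULL
  prov$n_out_of_extent <- prov$n_out_of_extent + n_drop
  new_occurrence_set(rec, prov)
}

# Full systematic-sampling chain: groves -> (optional) cell thinning -> clip.
# Returns the occurrence_set plus the presence cell indices on the stack.

#' Reduce raw records to modelling presences
#'
#' Runs the full systematic-sampling chain: collapse to grove centroids,
#' optionally thin to one record per raster cell, and clip to the stack's
#' valid extent. No geographic sampling-bias correction is applied.
#'
#' @param records Raw occurrence data.frame.
#' @param stack A [gn_stack] providing the lattice and valid mask.
#' @param dedupe_cells Thin to one record per cell (default TRUE).
#' @return An `occurrence_set` with an extra element `cells`: linear indices
#'   of the presence cells on the stack's grid.
#' @export
prepare_presences <- function(records, stack, dedupe_cells = TRUE) {
  occ <- collapse_to_groves(records)
  if (dedupe_cells) occ <- dedupe_per_cell(occ, stack$layers[[1]])
  occ <- clip_to_extent(occ, stack)
  occ$cells <- if (nrow(occ$records))
    cell_index(stack$layers[[1]], occ$records$lon, occ$records$lat)$cell
  else integer(0)
  occ
}
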