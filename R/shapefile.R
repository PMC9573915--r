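# Minimal ESRI shapefile support: polygon-type .shp plus the .dbf
# attribute table (.shx is redundant for sequential reads and is only
# required when writing).  Covers exactly what contiguity derivation
# needs; no projections, no M/Z coordinates.

read_uint32 <- function(raw, off, endian) {
  readBin(raw[(off + 1):(off + 4)], "integer", 1L, 4L, endian = endian)
}

#' Read a polygon shapefile
#'
#' Parses the `.shp` geometry file and the sibling `.dbf` attribute table.
#' Only shape type 5 (polygon) and type 0 (null, skipped with a warning)
#' records are supported.
#'
#' @param shp_path path to the `.shp` file (the `.dbf` is found by
#'   substituting the extension).
#' @return list with `shapes` (per record, a list of ring coordinate
#'   matrices with columns x, y) and `attributes` (data.frame from the
#'   `.dbf`, one row per record).
#' @export
read_shapefile <- function(shp_path) {
  if (!file.exists(shp_path)) stop("shapefile not found: ", shp_path)
  dbf_path <- sub("\\.shp$", ".dbf", shp_path, ignore.case = TRUE)
  if (identical(dbf_path, shp_path))
    stop("expected a path ending in .shp: ", shp_path)
  if (!file.exists(dbf_path)) stop("attribute table not found: ", dbf_path)

  raw <- readBin(shp_path, "raw", file.info(shp_path)$size)
  if (length(raw) < 100L) stop("unreadable shapefile (truncated header): ", shp_path)
  if (read_uint32(raw, 0L, "big") != 9994L)
    stop("unreadable shapefile (bad magic number): ", shp_path)
  file_len <- 2L * read_uint32(raw, 24L, "big")  # words -> bytes
  shapes <- list()
  off <- 100L
  while (off + 8L <= min(file_len, length(raw))) {
    content_len <- 2L * read_uint32(raw, off + 4L, "big")
    body <- off + 8L
    shp_type <- read_uint32(raw, body, "little")
    if (shp_type == 0L) {
      warning("null shape record skipped at byte offset ", off)
      shapes[[length(shapes) + 1L]] <- list()
    } else if (shp_type == 5L) {
      num_parts <- read_uint32(raw, body + 36L, "little")
      num_points <- read_uint32(raw, body + 40L, "little")
      parts <- readBin(raw[(body + 45L):(body + 44L + 4L * num_parts)],
                       "integer", num_parts, 4L, endian = "little")
      pts_off <- body + 44L + 4L * num_parts
      coords <- readBin(raw[(pts_off + 1L):(pts_off + 16L * num_points)],
                        "double", 2L * num_points, 8L, endian = "little")
      xy <- matrix(coords, ncol = 2L, byrow = TRUE,
                   dimnames = list(NULL, c("x", "y")))
      bounds <- c(parts, num_points)
      rings <- lapply(seq_len(num_parts), function(p)
        xy[(bounds[p] + 1L):bounds[p + 1L], , drop = FALSE])
      shapes[[length(shapes) + 1L]] <- rings
    } else {
      stop("unsupported shape type ", shp_type, " (only polygons are handled)")
    }
    off <- body + content_len
  }
  attributes <- read_dbf(dbf_path)
  if (nrow(attributes) != length(shapes))
    stop(sprintf("record count mismatch: %d shapes vs %d attribute rows",
                 length(shapes), nrow(attributes)))
  list(shapes = shapes, attributes = attributes)
}

read_dbf <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 33L) stop("unreadable .dbf (truncated): ", path)
  n_rec <- read_uint32(raw, 4L, "little")
  header_size <- readBin(raw[9:10], "integer", 1L, 2L, signed = FALSE,
                         endian = "little")
  record_size <- readBin(raw[11:12], "integer", 1L, 2L, signed = FALSE,
                         endian = "little")
  # field descriptors: 32 bytes each, from byte 32, until 0x0D terminator
  fields <- list()
  off <- 32L
  while (off + 1L <= header_size && raw[off + 1L] != as.raw(0x0D)) {
    blk <- raw[(off + 1L):(off + 32L)]
    nm_raw <- blk[1:11]
    nul <- which(nm_raw == as.raw(0))
    if (length(nul) > 0L) nm_raw <- nm_raw[seq_len(min(nul) - 1L)]
    name <- rawToChar(nm_raw)
    fields[[length(fields) + 1L]] <- list(
      name = name,
      type = rawToChar(blk[12L]),
      length = as.integer(blk[17L]),
      decimals = as.integer(blk[18L]))
    off <- off + 32L
  }
  widths <- vapply(fields, `[[`, integer(1), "length")
  cols <- lapply(fields, function(f) character(n_rec))
  for (r in seq_len(n_rec)) {
    roff <- header_size + (r - 1L) * record_size + 1L  # +1: deletion flag
    pos <- roff + 1L
    for (f in seq_along(fields)) {
      cols[[f]][r] <- rawToChar(raw[pos:(pos + widths[f] - 1L)])
      pos <- pos + widths[f]
    }
  }
  out <- lapply(seq_along(fields), function(f) {
    v <- trimws(cols[[f]])
    if (fields[[f]]$type %in% c("N", "F")) as.numeric(v) else v
  })
  names(out) <- vapply(fields, `[[`, character(1), "name")
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

# Fixture writer: polygons as list of ring lists (each ring an x,y matrix),
# one character attribute column.  Internal; used by the test-suite to
# materialize shapefiles programmatically.
write_shapefile <- function(path_stem, polygons, labels,
                            label_field = "NAME") {
  stopifnot(length(polygons) == length(labels))
  con_order <- function(x, endian) writeBin(x, raw(), endian = endian)
  rec_bodies <- lapply(polygons, function(rings) {
    rings <- lapply(rings, function(r) {
      r <- as.matrix(r)
      # close rings if open
      if (!all(r[1L, ] == r[nrow(r), ])) r <- rbind(r, r[1L, ])
      r
    })
    pts <- do.call(rbind, rings)
    parts <- cumsum(c(0L, vapply(rings, nrow, integer(1))))
    parts <- parts[-length(parts)]
    c(con_order(5L, "little"),
      con_order(c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2])), "little"),
      con_order(as.integer(c(length(rings), nrow(pts))), "little"),
      con_order(as.integer(parts), "little"),
      con_order(as.numeric(t(pts)), "little"))
  })
  all_pts <- do.call(rbind, lapply(polygons, function(r) do.call(rbind, lapply(r, as.matrix))))
  bbox <- c(min(all_pts[, 1]), min(all_pts[, 2]), max(all_pts[, 1]), max(all_pts[, 2]))
  header <- function(total_words) {
    c(con_order(c(9994L, 0L, 0L, 0L, 0L, 0L, total_words), "big"),
      con_order(c(1000L, 5L), "little"),
      con_order(c(bbox, 0, 0, 0, 0), "little"))
  }
  body <- raw(0)
  shx_recs <- raw(0)
  offset_words <- 50L
  for (i in seq_along(rec_bodies)) {
    clen <- length(rec_bodies[[i]]) / 2L
    body <- c(body, con_order(c(i, as.integer(clen)), "big"), rec_bodies[[i]])
    shx_recs <- c(shx_recs, con_order(c(offset_words, as.integer(clen)), "big"))
    offset_words <- offset_words + 4L + as.integer(clen)
  }
  writeBin(c(header(50L + length(body) %/% 2L), body),
           paste0(path_stem, ".shp"))
  writeBin(c(header(50L + length(shx_recs) %/% 2L), shx_recs),
           paste0(path_stem, ".shx"))
  write_dbf(paste0(path_stem, ".dbf"),
            stats::setNames(data.frame(as.character(labels),
                                       stringsAsFactors = FALSE),
                            label_field))
  invisible(paste0(path_stem, ".shp"))
}

write_dbf <- function(path, df) {
  stopifnot(is.data.frame(df), ncol(df) >= 1L)
  vals <- lapply(df, as.character)
  widths <- vapply(vals, function(v) max(1L, max(nchar(v))), integer(1))
  n_rec <- nrow(df)
  record_size <- 1L + sum(widths)
  header_size <- 32L + 32L * ncol(df) + 1L
  hdr <- c(as.raw(0x03), as.raw(c(95L, 1L, 1L)),
           writeBin(as.integer(n_rec), raw(), endian = "little"),
           writeBin(as.integer(header_size), raw(), size = 2L, endian = "little"),
           writeBin(as.integer(record_size), raw(), size = 2L, endian = "little"),
           raw(20L))
  for (f in seq_along(vals)) {
    nm <- charToRaw(substr(names(df)[f], 1L, 10L))
    desc <- c(nm, raw(11L - length(nm)), charToRaw("C"), raw(4L),
              as.raw(widths[f]), as.raw(0L), raw(14L))
    hdr <- c(hdr, desc)
  }
  hdr <- c(hdr, as.raw(0x0D))
  body <- raw(0)
  for (r in seq_len(n_rec)) {
    rec <- as.raw(0x20)
    for (f in seq_along(vals))
      rec <- c(rec, charToRaw(formatC(vals[[f]][r], width = -widths[f])))
    body <- c(body, rec)
  }
  writeBin(c(hdr, body, as.raw(0x1A)), path)
  invisible(path)
}

#' Derive a contiguity graph from polygon geometry
#'
#' Two polygons are first-order neighbours under the queen rule if their
#' boundaries share at least one vertex, and under the rook rule if they
#' share a boundary segment of positive length.  Shared points are matched
#' by exact coordinate equality after vertex deduplication (no snapping
#' tolerance), and vertex order follows shapefile record order so latent
#' field vectors align with input rows.
#'
#' @param shp_path path to a polygon `.shp` file.
#' @param contiguity_rule `"queen"` (default) or `"rook"`.
#' @param label_field name of the attribute column carrying region labels;
#'   `NULL` uses the first column.
#' @return a [spatial_graph()].
#' @export
polygons_to_graph <- function(shp_path, contiguity_rule = c("queen", "rook"),
                              label_field = NULL) {
  contiguity_rule <- match.arg(contiguity_rule)
  sf <- read_shapefile(shp_path)
  n <- length(sf$shapes)
  if (n < 2L) stop("shapefile must contain at least 2 polygons")
  if (is.null(label_field)) label_field <- names(sf$attributes)[1L]
  if (!label_field %in% names(sf$attributes))
    stop("label_field '", label_field, "' not present in attribute table; ",
         "available: ", paste(names(sf$attributes), collapse = ", "))
  labels <- as.character(sf$attributes[[label_field]])

  vkey <- function(xy) paste(sprintf("%.17g", xy[, 1L]),
                             sprintf("%.17g", xy[, 2L]), sep = "|")
  keysets <- lapply(sf$shapes, function(rings) {
    if (length(rings) == 0L) return(character(0))  # null shape
    if (contiguity_rule == "queen") {
      unique(unlist(lapply(rings, vkey)))
    } else {
      segs <- lapply(rings, function(r) {
        k <- vkey(r)
        a <- k[-length(k)]; b <- k[-1L]
        keep <- a != b  # drop zero-length segments
        paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]), sep = "~")
      })
      unique(unlist(segs))
    }
  })
  key_df <- data.frame(
    key = unlist(keysets),
    poly = rep.int(seq_len(n), lengths(keysets)),
    stringsAsFactors = FALSE)
  edges <- matrix(integer(0), ncol = 2L)
  if (nrow(key_df) > 0L) {
    grp <- split(key_df$poly, key_df$key)
    grp <- grp[lengths(grp) > 1L]
    if (length(grp) > 0L) {
      pair_up <- function(p) {
        p <- sort(unique(p))
        if (length(p) < 2L) return(NULL)
        t(utils::combn(p, 2L))
      }
      edges <- unique(do.call(rbind, lapply(grp, pair_up)))
    }
  }
  spatial_graph(edges, n, labels)
}
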