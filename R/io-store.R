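#' Write a mesh or point set to an ASCII PLY file
#'
#' @param x a [QuadMesh-class] (vertices + triangulated quads) or an
#'   N x 3 matrix of points (vertices only).
#' @param path output file.
#' @param colors optional N x 3 RGB matrix in \[0,1\] (written as uchar).
#' @return `path`, invisibly.
#' @export
writePLY <- function(x, path, colors = NULL) {
  if (is(x, "QuadMesh")) {
    tri <- meshTriangles(x)
    V <- tri$vertices; F <- tri$faces
  } else {
    V <- x; F <- NULL
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z"),
             con)
  if (!is.null(colors))
    writeLines(c("property uchar red", "property uchar green",
                 "property uchar blue"), con)
  if (!is.null(F))
    writeLines(sprintf("element face %d", nrow(F)), con)
  if (!is.null(F))
    writeLines("property list uchar int vertex_indices", con)
  writeLines("end_header", con)
  if (!is.null(colors)) {
    cc <- round(pmin(pmax(colors, 0), 1) * 255)
    writeLines(sprintf("%.6f %.6f %.6f %d %d %d", V[, 1], V[, 2], V[, 3],
                       cc[, 1], cc[, 2], cc[, 3]), con)
  } else {
    writeLines(sprintf("%.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
  }
  if (!is.null(F))
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1, F[, 2] - 1, F[, 3] - 1), con)
  invisible(path)
}

#' Read an ASCII PLY file
#'
#' Minimal reader for the files written by [writePLY()] (ASCII format,
#' x/y/z floats, optional uchar RGB, optional triangle faces).
#'
#' @param path PLY file.
#' @return List with `vertices` (N x 3), `faces` (M x 3, 1-based, or
#'   NULL) and `colors` (N x 3 in \[0,1\] or NULL).
#' @export
readPLY <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply")
    stop("integrity error: not a PLY file: ", path)
  endh <- which(lines == "end_header")[1]
  if (is.na(endh)) stop("integrity error: PLY header not terminated in ", path)
  head <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", head, value = TRUE)))
  nfLine <- grep("^element face", head, value = TRUE)
  nf <- if (length(nfLine)) as.integer(sub("element face ", "", nfLine)) else 0L
  hasColor <- any(grepl("property uchar red", head))
  if (length(lines) < endh + nv + nf)
    stop("integrity error: truncated PLY file ", path)
  vl <- strsplit(lines[(endh + 1):(endh + nv)], " ", fixed = TRUE)
  vm <- matrix(as.numeric(unlist(vl)), nrow = nv, byrow = TRUE)
  if (anyNA(vm[, 1:3])) stop("integrity error: bad vertex data in ", path)
  verts <- vm[, 1:3, drop = FALSE]
  colors <- if (hasColor && ncol(vm) >= 6) vm[, 4:6, drop = FALSE] / 255 else NULL
  faces <- NULL
  if (nf > 0) {
    fl <- strsplit(lines[(endh + nv + 1):(endh + nv + nf)], " ", fixed = TRUE)
    fm <- matrix(as.integer(unlist(fl)), nrow = nf, byrow = TRUE)
    faces <- fm[, 2:4, drop = FALSE] + 1L
  }
  list(vertices = verts, faces = faces, colors = colors)
}

#' Save a visit record to the store
#'
#' Writes the visit's report, perimeter, fiducials and tissue labels as
#' JSON plus the mesh as PLY under `store/patientId/date/`. Writes are
#' atomic (write-then-rename), so a crash mid-save leaves no partial
#' visit behind.
#'
#' @param record list with elements `patientId`, `date` (ISO-8601
#'   string), `report` ([WoundReport-class]), and optionally `mesh`
#'   ([QuadMesh-class]), `perimeter` (M x 3), `fiducials` (N x 3),
#'   `tissueLabels`.
#' @param storeDir store root directory (created if missing).
#' @param overwrite overwrite an existing visit with the same key.
#' @return The record key `"patientId/date"`, invisibly.
#' @export
saveVisit <- function(record, storeDir, overwrite = FALSE) {
  stopifnot(is.character(record$patientId), is.character(record$date))
  key <- file.path(record$patientId, record$date)
  dir <- file.path(storeDir, key)
  if (dir.exists(dir) && !overwrite)
    stop("duplicate visit key '", key, "' (use overwrite = TRUE)")
  tmp <- paste0(dir, ".tmp", Sys.getpid())
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    patient_id = record$patientId,
    date = record$date,
    report = as.list(reportValues(record$report)),
    tissue = as.list(record$report@tissue),
    meta = record$report@meta,
    perimeter = if (!is.null(record$perimeter)) unname(apply(record$perimeter, 1, as.numeric, simplify = FALSE)),
    fiducials = if (!is.null(record$fiducials)) unname(apply(record$fiducials, 1, as.numeric, simplify = FALSE)),
    tissue_labels = record$tissueLabels,
    mesh_file = if (!is.null(record$mesh)) "mesh.ply")
  jsonlite::write_json(meta, file.path(tmp, "visit.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(record$mesh)) writePLY(record$mesh, file.path(tmp, "mesh.ply"))
  if (dir.exists(dir)) unlink(dir, recursive = TRUE)
  dir.create(dirname(dir), recursive = TRUE, showWarnings = FALSE)
  if (!file.rename(tmp, dir)) stop("atomic rename failed for ", key)
  invisible(key)
}

#' List visit keys in a store
#' @param storeDir store root.
#' @return Character vector of `"patientId/date"` keys, sorted.
#' @export
listVisits <- function(storeDir) {
  pats <- list.dirs(storeDir, recursive = FALSE, full.names = FALSE)
  out <- character(0)
  for (p in pats) {
    dates <- list.dirs(file.path(storeDir, p), recursive = FALSE,
                       full.names = FALSE)
    out <- c(out, file.path(p, dates))
  }
  sort(out)
}

#' Load a visit record
#'
#' @param storeDir store root.
#' @param patientId patient identifier.
#' @param date ISO date string, or `"latest"` for the most recent visit,
#'   or `"previous"` together with `before` to get the latest visit
#'   strictly before that date.
#' @param before reference date for `date = "previous"`.
#' @return Record list as passed to [saveVisit()], with `report`
#'   rebuilt; `mesh` is loaded from PLY when present.
#' @export
loadVisit <- function(storeDir, patientId, date = "latest", before = NULL) {
  pdir <- file.path(storeDir, patientId)
  if (!dir.exists(pdir)) stop("not found: patient ", patientId)
  dates <- sort(list.dirs(pdir, recursive = FALSE, full.names = FALSE))
  if (!length(dates)) stop("not found: no visits for ", patientId)
  if (date == "latest") {
    date <- dates[length(dates)]
  } else if (date == "previous") {
    if (is.null(before)) stop("date = 'previous' needs `before`")
    cand <- dates[dates < before]
    if (!length(cand)) stop("not found: no visit before ", before)
    date <- cand[length(cand)]
  } else if (!date %in% dates) {
    stop("not found: visit ", patientId, "/", date)
  }
  dir <- file.path(pdir, date)
  meta <- jsonlite::fromJSON(file.path(dir, "visit.json"),
                             simplifyVector = TRUE)
  rv <- meta$report
  tissue <- unlist(meta$tissue) %||% numeric(0)
  report <- woundReport(depth = rv$depth_mm, perimeter = rv$perimeter_mm,
                        area3d = rv$area3d_mm2,
                        areaProjected = rv$areaproj_mm2,
                        axisMajor = rv$axis_major_mm,
                        axisMinor = rv$axis_minor_mm,
                        volume = rv$volume_mm3,
                        tissue = if (length(tissue)) tissue else numeric(0),
                        meta = as.list(meta$meta))
  mesh <- NULL
  if (!is.null(meta$mesh_file)) {
    ply <- readPLY(file.path(dir, meta$mesh_file))
    nv <- nrow(ply$vertices)
    r <- as.integer(round(sqrt(nv)))
    mesh <- if (r * r == nv) quadMesh(array(ply$vertices, c(r, r, 3))) else ply
  }
  asMat <- function(x) if (is.null(x) || !length(x)) NULL else
    matrix(as.numeric(if (is.list(x)) unlist(x) else t(x)), ncol = 3, byrow = TRUE)
  list(patientId = meta$patient_id, date = meta$date, report = report,
       mesh = mesh, perimeter = asMat(meta$perimeter),
       fiducials = asMat(meta$fiducials),
       tissueLabels = meta$tissue_labels)
}

#' Export a wound report
#'
#' @param record record list (as from [loadVisit()]) or a
#'   [WoundReport-class].
#' @param path output file.
#' @param format `"json"` (canonical) or `"csv"` (single row, stable
#'   header; composition fractions with 4 decimals).
#' @return `path`, invisibly.
#' @export
exportReport <- function(record, path, format = c("json", "csv")) {
  format <- match.arg(format)
  report <- if (is(record, "WoundReport")) record else record$report
  v <- reportValues(report)
  tissue <- report@tissue
  if (format == "json") {
    out <- as.list(v)
    if (length(tissue)) out$tissue <- as.list(round(tissue, 4))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    tcols <- c("granulation", "slough", "necrosis")
    tv <- setNames(rep(NA_real_, 3), tcols)
    tv[names(tissue)] <- round(tissue, 4)
    df <- cbind(as.data.frame(as.list(v)),
                as.data.frame(as.list(tv)))
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
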