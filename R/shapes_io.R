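#' Construct a specimen shape
#'
#' A `specimen_shape` holds one specimen's digitized 2D landmark configuration
#' for one anatomical view, together with its provenance: the side the bone
#' came from, the physical scale the coordinates were multiplied by, and an
#' optional image reference.
#'
#' @param specimen_id Character scalar identifying the specimen.
#' @param view One of the canonical views: `r paste(LOCOMORPH_VIEWS, collapse = ", ")`,
#'   or any other label for non-standard schemes.
#' @param points Numeric matrix with two columns (x, y), coordinates in mm.
#' @param side `"left"` or `"right"`. Analyses expect left-standardized data;
#'   see [mirror_reflect()].
#' @param scale_mm_per_unit Positive scale already applied to `points`
#'   (retained as provenance; stored coordinates are always in mm).
#' @param image_ref Optional character, e.g. the source photograph name.
#' @return An object of class `specimen_shape`.
#' @export
specimen_shape <- function(specimen_id, view, points, side = "left",
                           scale_mm_per_unit = 1, image_ref = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must have two columns (x, y)")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop("all coordinates must be finite")
  if (!is.numeric(scale_mm_per_unit) || scale_mm_per_unit <= 0) {
    stop("`scale_mm_per_unit` must be strictly positive")
  }
  side <- match.arg(side, c("left", "right"))
  structure(
    list(
      specimen_id = as.character(specimen_id),
      view = as.character(view),
      points = unname(points),
      side = side,
      scale_mm_per_unit = as.numeric(scale_mm_per_unit),
      image_ref = image_ref
    ),
    class = "specimen_shape"
  )
}

#' @export
print.specimen_shape <- function(x, ...) {
  cat(sprintf(
    "<specimen_shape> %s  view=%s  side=%s  %d landmarks\n",
    x$specimen_id, x$view, x$side, nrow(x$points)
  ))
  invisible(x)
}

#' Read a TPS landmark file
#'
#' Parses the TPS format written by common digitizers. Each record starts
#' with `LM=<k>` followed by `k` coordinate lines; optional `CURVES=<m>`
#' blocks (each `POINTS=<p>` followed by `p` coordinate lines) are appended
#' after the fixed landmarks in file order. `ID=` (preferred) or `IMAGE=`
#' supplies the specimen id; `SCALE=` (default 1) multiplies all coordinates
#' so stored points are in mm.
#'
#' Files produced with image-origin conventions (y increasing downward) are
#' not auto-flipped; pass `flip_y = TRUE` to negate y explicitly.
#'
#' @param path Path to the TPS file.
#' @param view View label attached to every record.
#' @param flip_y If `TRUE`, negate y coordinates after reading.
#' @return List of [specimen_shape()] objects, in record order.
#' @export
read_tps <- function(path, view = "trochlear", flip_y = FALSE) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  shapes <- list()
  i <- 1L
  n_lines <- length(lines)
  rec <- 0L

  read_coords <- function(i, k, what) {
    pts <- matrix(NA_real_, k, 2L)
    for (j in seq_len(k)) {
      while (i <= n_lines && !nzchar(lines[i])) i <- i + 1L
      if (i > n_lines) {
        stop(sprintf("record %d: expected %d %s lines, file ended early", rec, k, what))
      }
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "[,[:space:]]+")[[1]]))
      if (length(xy) < 2L || anyNA(xy[1:2])) {
        stop(sprintf("record %d: non-numeric coordinate at line %d", rec, i))
      }
      pts[j, ] <- xy[1:2]
      i <- i + 1L
    }
    list(pts = pts, i = i)
  }

  while (i <= n_lines) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      stop(sprintf("expected 'LM=' at line %d, got: %s", i, lines[i]))
    }
    rec <- rec + 1L
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE)))
    if (is.na(k) || k < 0L) stop(sprintf("record %d: malformed LM count at line %d", rec, i))
    i <- i + 1L
    got <- read_coords(i, k, "landmark"); fixed <- got$pts; i <- got$i

    curves <- NULL
    id <- NA_character_; image <- NA_character_; scale <- 1
    while (i <= n_lines && nzchar(lines[i]) &&
           !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      ln <- lines[i]
      if (grepl("^CURVES\\s*=", ln, ignore.case = TRUE)) {
        m <- as.integer(sub("^CURVES\\s*=\\s*", "", ln, ignore.case = TRUE))
        i <- i + 1L
        for (ci in seq_len(m)) {
          while (i <= n_lines && !nzchar(lines[i])) i <- i + 1L
          if (i > n_lines || !grepl("^POINTS\\s*=", lines[i], ignore.case = TRUE)) {
            stop(sprintf("record %d: CURVES=%d but POINTS= block %d missing", rec, m, ci))
          }
          p <- as.integer(sub("^POINTS\\s*=\\s*", "", lines[i], ignore.case = TRUE))
          i <- i + 1L
          got <- read_coords(i, p, "curve point"); i <- got$i
          curves <- rbind(curves, got$pts)
        }
      } else if (grepl("^IMAGE\\s*=", ln, ignore.case = TRUE)) {
        image <- sub("^IMAGE\\s*=\\s*", "", ln, ignore.case = TRUE); i <- i + 1L
      } else if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE); i <- i + 1L
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", ln, ignore.case = TRUE))
        if (is.na(scale) || scale <= 0) {
          stop(sprintf("record %d: bad SCALE at line %d", rec, i))
        }
        i <- i + 1L
      } else {
        # unknown key: tolerate and skip
        i <- i + 1L
      }
    }

    pts <- rbind(fixed, curves) * scale
    if (flip_y) pts[, 2] <- -pts[, 2]
    sid <- if (!is.na(id) && nzchar(id)) id else if (!is.na(image)) image else sprintf("record_%d", rec)
    shapes[[rec]] <- specimen_shape(
      specimen_id = sid, view = view, points = pts,
      scale_mm_per_unit = scale,
      image_ref = if (!is.na(image)) image else NULL
    )
  }
  shapes
}

#' Write shapes to a TPS file
#'
#' Emits one record per shape with `LM=`, coordinate lines, optional
#' `IMAGE=`, `ID=` and `SCALE=1.0` (stored coordinates are already in mm).
#' Output is deterministic, so files are bit-stable across runs.
#'
#' @param shapes Non-empty list of [specimen_shape()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(shapes, path) {
  if (length(shapes) == 0L) stop("`shapes` must be a non-empty list")
  if (inherits(shapes, "specimen_shape")) shapes <- list(shapes)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in shapes) {
    stopifnot(inherits(s, "specimen_shape"))
    writeLines(sprintf("LM=%d", nrow(s$points)), con)
    writeLines(sprintf("%.15g %.15g", s$points[, 1], s$points[, 2]), con)
    if (!is.null(s$image_ref)) writeLines(paste0("IMAGE=", s$image_ref), con)
    writeLines(paste0("ID=", s$specimen_id), con)
    writeLines("SCALE=1.0", con)
  }
  invisible(path)
}

#' Construct a slider table
#'
#' Each row names a sliding semilandmark and its two neighbours defining the
#' tangent it slides along during superimposition. Indices are 1-based, the
#' same convention used in slider files and reports.
#'
#' @param before,slider,after Integer vectors of landmark indices.
#' @param n_landmarks Optional bound for index validation.
#' @return Integer matrix of class `slider_table` with columns
#'   `before`, `slider`, `after`.
#' @export
slider_table <- function(before, slider, after, n_landmarks = NULL) {
  m <- cbind(before = as.integer(before), slider = as.integer(slider),
             after = as.integer(after))
  if (nrow(m) > 0L) {
    if (anyNA(m) || any(m < 1L)) stop("slider indices must be positive integers")
    bad <- which(m[, 1] == m[, 2] | m[, 2] == m[, 3] | m[, 1] == m[, 3])
    if (length(bad)) stop("slider rows with non-distinct indices: ", paste(bad, collapse = ", "))
    dup <- duplicated(m[, 2])
    if (any(dup)) {
      stop("semilandmark(s) listed as slider more than once: ",
           paste(unique(m[dup, 2]), collapse = ", "))
    }
    if (!is.null(n_landmarks) && any(m > n_landmarks)) {
      bad <- which(apply(m, 1L, function(r) any(r > n_landmarks)))
      stop("slider indices out of range (n = ", n_landmarks, ") in row(s): ",
           paste(bad, collapse = ", "))
    }
  }
  structure(m, class = c("slider_table", class(m)))
}

#' Read a slider-definition table
#'
#' Accepts whitespace- or comma-delimited triples `before slider after`
#' (1-based indices, one row per sliding semilandmark), with an optional
#' header line.
#'
#' @param path Path to the slider file.
#' @param n_landmarks Optional landmark count for bounds checking.
#' @return A [slider_table()].
#' @export
read_sliders <- function(path, n_landmarks = NULL) {
  if (!file.exists(path)) stop("slider file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    suppressWarnings(as.integer(strsplit(ln, "[,[:space:]]+")[[1]]))
  })
  if (length(rows) && anyNA(rows[[1]])) rows <- rows[-1L]  # header
  if (!length(rows)) return(slider_table(integer(), integer(), integer()))
  if (any(vapply(rows, function(r) length(r) < 3L || anyNA(r[1:3]), logical(1)))) {
    stop("slider file must contain integer triples: ", path)
  }
  m <- do.call(rbind, lapply(rows, function(r) r[1:3]))
  slider_table(m[, 1], m[, 2], m[, 3], n_landmarks = n_landmarks)
}

#' Write a slider table
#'
#' @param sliders A [slider_table()].
#' @param path Output path; written as whitespace-delimited triples with a
#'   header line.
#' @return `path`, invisibly.
#' @export
write_sliders <- function(sliders, path) {
  df <- as.data.frame(unclass(sliders))
  utils::write.table(df, path, sep = " ", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read specimen metadata
#'
#' CSV with required columns `specimen_id`, `taxon`, `ecology_bin`
#' (`arboreal_scansorial`, `terrestrial_saltating` or `unassigned`) and
#' `is_fossil` (logical). Fossils must be unassigned: ecology bins are
#' defined from extant taxa of known habits only.
#'
#' @param path CSV path.
#' @return A data.frame of validated metadata.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("specimen_id", "taxon", "ecology_bin", "is_fossil")
  missing <- setdiff(req, names(md))
  if (length(missing)) stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  md$is_fossil <- as.logical(md$is_fossil)
  bad <- setdiff(unique(md$ecology_bin), LOCOMORPH_BINS)
  if (length(bad)) stop("unknown ecology_bin value(s): ", paste(bad, collapse = ", "))
  viol <- md$is_fossil & md$ecology_bin != "unassigned"
  if (any(viol)) {
    stop("fossil specimens must be unassigned: ",
         paste(md$specimen_id[viol], collapse = ", "))
  }
  if (anyDuplicated(md$specimen_id)) {
    stop("duplicate specimen_id in metadata: ",
         paste(unique(md$specimen_id[duplicated(md$specimen_id)]), collapse = ", "))
  }
  md
}

#' Read a linear-measurement table
#'
#' CSV with `specimen_id` plus the eight standardized astragalar measurements
#' in mm: ML (max anteroposterior length), MW (max width), MD (max depth on
#' the lateral side), HNF and WNF (navicular facet height and width), LLTC
#' and LMTC (lateral and medial trochlear crest lengths), WTS (articular
#' sulcus width). All values must be strictly positive.
#'
#' @param path CSV path.
#' @return A data.frame with `specimen_id` and the eight measurement columns.
#' @export
read_measurements <- function(path) {
  mm <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("specimen_id", MEASUREMENT_VARS)
  missing <- setdiff(req, names(mm))
  if (length(missing)) stop("measurements missing column(s): ", paste(missing, collapse = ", "))
  for (v in MEASUREMENT_VARS) {
    bad <- !is.finite(mm[[v]]) | mm[[v]] <= 0
    if (any(bad)) {
      stop(sprintf("non-positive or non-finite %s for specimen(s): %s",
                   v, paste(mm$specimen_id[bad], collapse = ", ")))
    }
  }
  mm[, req]
}

#' Validate a landmark dataset against its metadata and scheme
#'
#' Report-only consistency check: flags shapes lacking metadata, point-count
#' mismatches against the scheme, duplicate specimen ids, metadata invariant
#' violations (labelled fossils), and counts specimens per ecology bin.
#'
#' @param shapes List of [specimen_shape()] objects.
#' @param metadata Data.frame from [read_metadata()] (or equivalent).
#' @param scheme Optional [landmark_scheme()]; if given, point counts are
#'   checked against [scheme_total()].
#' @return A list of class `validation_report` with elements `issues`
#'   (data.frame: `type`, `specimen_id`, `detail`) and `bin_counts`.
#' @export
validate_dataset <- function(shapes, metadata, scheme = NULL) {
  issues <- data.frame(type = character(), specimen_id = character(),
                       detail = character(), stringsAsFactors = FALSE)
  add <- function(type, id, detail) {
    issues[nrow(issues) + 1L, ] <<- list(type, id, detail)
  }
  ids <- vapply(shapes, function(s) s$specimen_id, character(1))
  for (id in unique(ids[duplicated(ids)])) {
    add("duplicate_id", id, sprintf("appears %d times", sum(ids == id)))
  }
  for (s in shapes) {
    if (!s$specimen_id %in% metadata$specimen_id) {
      add("missing_metadata", s$specimen_id, "no metadata row")
    }
    if (!is.null(scheme)) {
      want <- scheme_total(scheme)
      if (nrow(s$points) != want) {
        add("point_count", s$specimen_id,
            sprintf("has %d landmarks, scheme expects %d", nrow(s$points), want))
      }
    }
  }
  md <- metadata[metadata$specimen_id %in% ids, , drop = FALSE]
  viol <- md$is_fossil & md$ecology_bin != "unassigned"
  for (id in md$specimen_id[viol]) {
    add("fossil_labelled", id, "fossil carries an ecology bin")
  }
  assigned <- md[!md$is_fossil & md$ecology_bin != "unassigned", , drop = FALSE]
  bin_counts <- table(factor(assigned$ecology_bin,
                             levels = setdiff(LOCOMORPH_BINS, "unassigned")))
  for (b in names(bin_counts)) {
    if (bin_counts[[b]] > 0L && bin_counts[[b]] < 2L) {
      add("small_bin", "", sprintf("bin %s has %d specimen(s); >= 2 needed for training", b, bin_counts[[b]]))
    }
  }
  structure(list(issues = issues, bin_counts = bin_counts),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x$issues) == 0L) {
    cat("validation: no issues\n")
  } else {
    cat(sprintf("validation: %d issue(s)\n", nrow(x$issues)))
    print(x$issues, row.names = FALSE)
  }
  cat("specimens per assigned ecology bin:\n")
  print(x$bin_counts)
  invisible(x)
}
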