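#' Plan bundle
#'
#' One treatment plan as the metric engine consumes it: a dose grid and a
#' structure set on a single shared voxel grid, plus provenance notes
#' recording where the data came from and what resampling was applied at
#' ingest.
#'
#' @param plan_id identifier.
#' @param dose a [dose_grid].
#' @param structures named list of [structure_mask] objects on the same
#'   grid as the dose.
#' @param provenance character vector of free-text provenance lines.
#' @return object of class `plan_bundle`.
#' @export
plan_bundle <- function(plan_id, dose, structures, provenance = character()) {
  stopifnot(inherits(dose, "dose_grid"), is.list(structures))
  for (m in structures)
    stop_if_geometry_mismatch(dose$geometry, m$geometry,
                              sprintf("dose grid and structure '%s'", m$name))
  structure(list(plan_id = plan_id, dose = dose, structures = structures,
                 provenance = provenance),
            class = "plan_bundle")
}

#' @export
print.plan_bundle <- function(x, ...) {
  cat(sprintf("plan bundle '%s': %d structures (%s)\n", x$plan_id,
              length(x$structures), paste(names(x$structures), collapse = ", ")))
  print(x$dose)
  invisible(x)
}

BUNDLE_MAGIC <- "KBPBUNDLE"
BUNDLE_VERSION <- 1L

# run-length encode the linear indices of set voxels as "a" / "a:b" tokens
rle_encode_indices <- function(idx) {
  if (length(idx) == 0) return(character())
  brk <- c(0, which(diff(idx) != 1), length(idx))
  vapply(seq_len(length(brk) - 1), function(k) {
    a <- idx[brk[k] + 1]; b <- idx[brk[k + 1]]
    if (a == b) sprintf("%d", a) else sprintf("%d:%d", a, b)
  }, "")
}

rle_decode_indices <- function(tokens) {
  if (length(tokens) == 0) return(integer())
  unlist(lapply(tokens, function(t) {
    p <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (length(p) == 1) as.integer(p) else seq.int(as.integer(p[1]), as.integer(p[2]))
  }))
}

#' Write / read a plan bundle in the portable text format
#'
#' A single plain-text file: a versioned header, a YAML metadata block
#' (plan id, grid geometry, prescription, provenance, structure roster),
#' the dose values at full double precision (one z-slice per line), and
#' each mask as run-length-encoded linear voxel indices. The round trip is
#' lossless: arrays are restored bit-identically.
#'
#' @param bundle a [plan_bundle].
#' @param path file path (conventionally `.kbp`).
#' @return `read_bundle` returns a [plan_bundle]; `write_bundle` returns
#'   `path` invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "plan_bundle"))
  g <- bundle$dose$geometry
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s %d", BUNDLE_MAGIC, BUNDLE_VERSION), con)
  meta <- list(plan_id = bundle$plan_id,
               origin = g$origin, spacing = g$spacing, dim = g$dim,
               prescription_dose = bundle$dose$prescription_dose,
               provenance = as.list(bundle$provenance),
               structures = lapply(unname(bundle$structures), function(m)
                 list(name = m$name, role = m$role,
                      n_voxels = sum(m$occupancy))))
  writeLines("#META", con)
  writeLines(yaml::as.yaml(meta), con)
  writeLines("#DOSE", con)
  d <- bundle$dose$dose
  for (k in seq_len(g$dim[3]))
    writeLines(paste(sprintf("%.17g", d[, , k]), collapse = " "), con)
  for (m in bundle$structures) {
    writeLines(sprintf("#MASK %s %s", m$name, m$role), con)
    writeLines(paste(rle_encode_indices(which(m$occupancy)), collapse = " "), con)
  }
  writeLines("#END", con)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("truncated bundle file")
  head <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (length(head) != 2 || head[1] != BUNDLE_MAGIC)
    stop("not a kbpaudit bundle file")
  if (as.integer(head[2]) != BUNDLE_VERSION)
    stop(sprintf("bundle format version %s is not supported (expected %d)",
                 head[2], BUNDLE_VERSION))
  if (!identical(lines[length(lines)], "#END"))
    stop("truncated bundle file (missing #END)")
  sec <- grep("^#(META|DOSE|MASK |END)", lines)
  if (!identical(lines[sec[1]], "#META") || !("#DOSE" %in% lines))
    stop("malformed bundle file")
  meta_lines <- lines[(sec[1] + 1):(sec[2] - 1)]
  meta <- yaml::yaml.load(paste(meta_lines, collapse = "\n"))
  g <- grid_geometry(as.numeric(meta$origin), as.numeric(meta$spacing),
                     as.integer(meta$dim))
  dose_start <- which(lines == "#DOSE")
  nz <- g$dim[3]
  if (dose_start + nz > length(lines)) stop("truncated bundle file (dose block)")
  dose <- array(0, g$dim)
  for (k in seq_len(nz)) {
    v <- as.numeric(strsplit(lines[dose_start + k], " ", fixed = TRUE)[[1]])
    if (length(v) != g$dim[1] * g$dim[2])
      stop("truncated bundle file (dose slice length)")
    dose[, , k] <- v
  }
  dg <- dose_grid(dose, g, as.numeric(meta$prescription_dose))
  mask_at <- grep("^#MASK ", lines)
  structures <- list()
  for (i in mask_at) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    occ <- array(FALSE, g$dim)
    toks <- strsplit(trimws(lines[i + 1]), " ", fixed = TRUE)[[1]]
    occ[rle_decode_indices(toks[nzchar(toks)])] <- TRUE
    structures[[hdr[2]]] <- structure_mask(occ, g, hdr[2], hdr[3])
  }
  expected <- vapply(meta$structures, `[[`, "", "name")
  if (!setequal(expected, names(structures)))
    stop("bundle structure roster does not match the mask blocks")
  plan_bundle(meta$plan_id, dg, structures,
              provenance = unlist(meta$provenance))
}
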