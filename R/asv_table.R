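#' Construct and validate an ASV count table
#'
#' An `asv_table` is the package's universal community currency: a
#' samples-by-ASVs matrix of non-negative integer read counts with unique
#' sample and ASV identifiers, tagged by the marker gene it derives from
#' (16S rRNA for prokaryotes, 18S rRNA for eukaryotes).
#'
#' @param counts numeric matrix, samples in rows, ASVs in columns, with
#'   `rownames` (sample ids) and `colnames` (ASV ids).
#' @param marker `"16S"` or `"18S"`.
#' @return An object of class `asv_table`: the validated integer count matrix
#'   with a `marker` attribute.
#' @export
asv_table <- function(counts, marker = c("16S", "18S")) {
  marker <- match.arg(marker)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample ids (rownames) and ASV ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate ASV id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts)) {
    bad <- which(is.na(suppressWarnings(as.numeric(counts))))[1]
    stop("non-numeric count at [",
         rownames(counts)[(bad - 1) %% nrow(counts) + 1], ", ",
         colnames(counts)[(bad - 1) %/% nrow(counts) + 1], "]")
  }
  if (anyNA(counts) || any(counts < 0)) {
    bad <- which(is.na(counts) | counts < 0, arr.ind = TRUE)[1, ]
    stop("negative or missing count at [", rownames(counts)[bad[1]], ", ",
         colnames(counts)[bad[2]], "]")
  }
  if (any(abs(counts - round(counts)) > 1e-8))
    warning("non-integer counts rounded to nearest integer")
  storage.mode(counts) <- "double"
  counts <- round(counts)
  structure(counts, marker = marker, class = c("asv_table", "matrix", "array"))
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table (%s): %d samples x %d ASVs, %s total reads\n",
              attr(x, "marker"), nrow(x), ncol(x),
              format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Read a delimited ASV count table
#'
#' Reads a TSV/CSV count table with a header row and an identifier first
#' column. The canonical internal orientation is samples-as-rows; when
#' `orientation = "auto"` the reader transposes tables whose first column
#' contains many more entries than the header (the common QIIME2 export with
#' ASVs as rows), or honours an explicit setting.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.csv` means comma, anything else tab) unless `sep` is given.
#' @param marker `"16S"` or `"18S"`.
#' @param orientation `"auto"`, `"samples_rows"`, or `"asvs_rows"`.
#' @param sep field separator override.
#' @return An [asv_table].
#' @export
read_asv_table <- function(path, marker = c("16S", "18S"),
                           orientation = c("auto", "samples_rows", "asvs_rows"),
                           sep = NULL) {
  marker <- match.arg(marker)
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("no samples: table at ", path, " is empty")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rownames(m) <- ids
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("non-numeric count at [", rownames(m)[bad[1, 1]], ", ",
           colnames(m)[bad[1, 2]], "]")
    storage.mode(m) <- "double"
  }
  if (orientation == "asvs_rows" ||
      (orientation == "auto" && nrow(m) > 3 * ncol(m))) {
    m <- t(m)
  }
  asv_table(m, marker)
}

#' Rarefy an ASV table to even sequencing depth
#'
#' Subsamples each sample's reads without replacement to a common depth, so
#' that downstream relative abundances are comparable across samples with
#' unequal sequencing effort. Samples with fewer total reads than `depth`
#' are dropped (and reported via the `"dropped_samples"` attribute).
#'
#' @param x an [asv_table].
#' @param depth target row total; default is the minimum row total across
#'   samples, so no sample is dropped.
#' @param seed integer seed (mandatory: rarefaction is a random draw).
#' @return A rarefied [asv_table] whose retained rows all sum to `depth`;
#'   attributes `depth`, `seed` and `dropped_samples` record the operation.
#' @export
rarefy <- function(x, depth = NULL, seed) {
  stopifnot(inherits(x, "asv_table"))
  if (missing(seed)) stop("a seed is required for rarefaction")
  totals <- rowSums(x)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be >= 1")
  if (all(totals < depth))
    stop("depth ", depth, " exceeds every sample total (max ", max(totals), ")")
  keep <- totals >= depth
  dropped <- rownames(x)[!keep]
  if (length(dropped) > 0)
    message("rarefy: dropping ", length(dropped), " sample(s) below depth ",
            depth, ": ", paste(dropped, collapse = ", "))
  m <- unclass(x)[keep, , drop = FALSE]
  set.seed(seed)
  # hypergeometric draw per sample; rrarefy's "observed counts" heuristic
  # warning is moot here because the constructor has already validated the
  # counts as non-negative integers
  out <- suppressWarnings(vegan::rrarefy(m, depth))
  res <- asv_table(out, attr(x, "marker"))
  attr(res, "depth") <- depth
  attr(res, "seed") <- seed
  attr(res, "dropped_samples") <- dropped
  res
}

#' Relative abundance matrix
#'
#' @param x an [asv_table] or non-negative matrix with positive row totals.
#' @return Matrix of per-sample proportions; each row sums to 1. Multiply by
#'   100 for the relative percent abundances reported in survey summaries.
#' @export
relative_abundance <- function(x) {
  m <- unclass(x)
  totals <- rowSums(m)
  if (any(totals <= 0))
    stop("zero-total row(s): ", paste(rownames(m)[totals <= 0], collapse = ", "))
  sweep(m, 1, totals, "/")
}

# Diatom and other photosynthesising stramenopile classes retained in the
# Stramenopiles_photosynthetic group; all other stramenopiles are "Other".
PHOTOSYNTHETIC_STRAMENOPILE_CLASSES <- c(
  "Coscinodiscophyceae", "Bacillariophyceae", "Mediophyceae",
  "Chrysophyceae", "Bolidophyceae", "Dictyochophyceae",
  "Pelagophyceae", "Pinguiophyceae"
)

#' Phytoplankton group labels used throughout the pipeline
#' @export
PHYTO_GROUPS <- c("Prochlorococcus", "Synechococcus", "Archaeplastida",
                  "Dinoflagellata", "Haptophyta", "Stramenopiles_photosynthetic")

#' Read a taxonomy map
#'
#' Accepts the QIIME2-style two-column export (`Feature ID`, `Taxon`) with
#' semicolon-delimited ranked lineages.
#'
#' @param path TSV file path.
#' @return data.frame with columns `asv_id` and `lineage`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (ncol(df) < 2) stop("taxonomy file needs id and lineage columns")
  out <- data.frame(asv_id = as.character(df[[1]]),
                    lineage = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$asv_id))
    stop("duplicate ASV id in taxonomy: ",
         paste(unique(out$asv_id[duplicated(out$asv_id)]), collapse = ", "))
  out
}

#' Assign ASVs to major phytoplankton-containing groups
#'
#' Deterministically maps ranked lineages to the six phytoplankton-containing
#' groups analysed throughout: the cyanobacterial genera *Prochlorococcus*
#' and *Synechococcus* (16S); the eukaryotic divisions Archaeplastida,
#' Dinoflagellata and Haptophyta (18S); and photosynthesising Stramenopiles,
#' retained only when the lineage contains one of the diatom classes
#' Coscinodiscophyceae, Bacillariophyceae or Mediophyceae or the classes
#' Chrysophyceae, Bolidophyceae, Dictyochophyceae, Pelagophyceae or
#' Pinguiophyceae. Everything else (e.g. Opisthokonta, heterotrophic
#' bacteria) is labelled `"Other"`.
#'
#' @param taxonomy data.frame with `asv_id` and `lineage` (semicolon-delimited
#'   ranks), as returned by [read_taxonomy()].
#' @param asv_ids optional ids to label; ids missing from `taxonomy` get
#'   `"Other"` with a warning.
#' @return Named character vector: `asv_id -> group`.
#' @export
assign_groups <- function(taxonomy, asv_ids = NULL) {
  stopifnot(all(c("asv_id", "lineage") %in% names(taxonomy)))
  lab <- vapply(taxonomy$lineage, .group_from_lineage, character(1), USE.NAMES = FALSE)
  names(lab) <- taxonomy$asv_id
  if (!is.null(asv_ids)) {
    missing <- setdiff(asv_ids, names(lab))
    if (length(missing) > 0) {
      warning(length(missing), " ASV(s) missing from taxonomy; labelled Other")
      lab <- c(lab, stats::setNames(rep("Other", length(missing)), missing))
    }
    lab <- lab[asv_ids]
  }
  lab
}

.group_from_lineage <- function(lineage) {
  ranks <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  ranks <- sub("^[a-z]__", "", ranks)          # strip QIIME2 rank prefixes
  has <- function(x) any(tolower(ranks) %in% tolower(x))
  if (has("Prochlorococcus") ||
      any(grepl("^Prochlorococcus", ranks, ignore.case = TRUE))) return("Prochlorococcus")
  if (has("Synechococcus") ||
      any(grepl("^Synechococcus", ranks, ignore.case = TRUE))) return("Synechococcus")
  if (has("Dinoflagellata") || has("Dinophyceae")) return("Dinoflagellata")
  if (has("Haptophyta")) return("Haptophyta")
  if (has("Stramenopiles") || has("Ochrophyta")) {
    if (has(PHOTOSYNTHETIC_STRAMENOPILE_CLASSES)) return("Stramenopiles_photosynthetic")
    return("Other")
  }
  if (has("Archaeplastida") || has("Chlorophyta")) return("Archaeplastida")
  "Other"
}

#' Classify ASVs as persistent or ephemeral across yearly surveys
#'
#' An ASV is *detected* in a year when its count exceeds zero in at least one
#' sample of that year's table. ASVs detected in all three years are
#' *persistent*; those detected in one or two years are *ephemeral*. ASVs
#' present in the tables but detected nowhere (e.g. zeroed out by
#' rarefaction) are excluded with a warning.
#'
#' @param tables_by_year named list of exactly three [asv_table] objects,
#'   names giving the survey years.
#' @return data.frame with columns `asv_id`, `label`
#'   (`"persistent"`/`"ephemeral"`), `n_years`, and `years` (comma-joined
#'   years of detection).
#' @export
classify_persistence <- function(tables_by_year) {
  if (length(tables_by_year) != 3L)
    stop("exactly three yearly tables are required, got ", length(tables_by_year))
  if (is.null(names(tables_by_year))) stop("tables_by_year must be named by year")
  det <- lapply(tables_by_year, function(t) {
    stopifnot(inherits(t, "asv_table"))
    ids <- colnames(t)[colSums(unclass(t) > 0) > 0]
    ids
  })
  all_ids <- unique(unlist(lapply(tables_by_year, colnames)))
  years <- names(tables_by_year)
  hit <- vapply(det, function(ids) all_ids %in% ids, logical(length(all_ids)))
  n_years <- rowSums(hit)
  absent <- all_ids[n_years == 0]
  if (length(absent) > 0)
    warning(length(absent), " ASV(s) absent in all years excluded from persistence labels")
  keep <- n_years > 0
  data.frame(
    asv_id = all_ids[keep],
    label = ifelse(n_years[keep] == 3L, "persistent", "ephemeral"),
    n_years = n_years[keep],
    years = apply(hit[keep, , drop = FALSE], 1,
                  function(h) paste(years[h], collapse = ",")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Assign samples to biogeographic regions
#'
#' The transect is partitioned by two frontal features: a salinity front
#' (default 34.82 ppt) marking the northern edge of the North Pacific
#' Subtropical Gyre, and a chlorophyll-a front (default 0.15 mg m^-3)
#' separating the southern (STZ) and northern (NTZ) subregions of the
#' transition zone. With per-sample hydrography: NPSG when salinity exceeds
#' the salinity cut; otherwise NTZ when chlorophyll reaches the chlorophyll
#' cut, else STZ. When hydrography is missing, interpolated front latitudes
#' (per year) are used instead; samples with neither are `"unassigned"`.
#'
#' @param meta data.frame with columns `salinity`, `chlorophyll`, and
#'   optionally `latitude` and `year`.
#' @param salinity_cut,chl_cut front definitions (ppt, mg m^-3).
#' @param front_latitudes optional data.frame with columns `year`,
#'   `salinity_front_lat`, `chl_front_lat` for the hydrography-free fallback.
#' @return character vector of regions in `{"NPSG","STZ","NTZ","unassigned"}`.
#' @export
assign_region <- function(meta, salinity_cut = 34.82, chl_cut = 0.15,
                          front_latitudes = NULL) {
  n <- nrow(meta)
  sal <- if ("salinity" %in% names(meta)) meta$salinity else rep(NA_real_, n)
  chl <- if ("chlorophyll" %in% names(meta)) meta$chlorophyll else rep(NA_real_, n)
  region <- rep("unassigned", n)
  ok <- is.finite(sal) & is.finite(chl)
  region[ok & sal > salinity_cut] <- "NPSG"
  region[ok & sal <= salinity_cut & chl >= chl_cut] <- "NTZ"
  region[ok & sal <= salinity_cut & chl < chl_cut] <- "STZ"
  todo <- !ok
  if (any(todo) && !is.null(front_latitudes) &&
      all(c("latitude", "year") %in% names(meta))) {
    fl <- front_latitudes
    for (i in which(todo)) {
      row <- fl[fl$year == meta$year[i], , drop = FALSE]
      if (nrow(row) != 1 || !is.finite(meta$latitude[i])) next
      lat <- meta$latitude[i]
      region[i] <- if (lat < row$salinity_front_lat) "NPSG"
                   else if (lat >= row$chl_front_lat) "NTZ" else "STZ"
    }
  }
  if (any(region == "unassigned"))
    warning(sum(region == "unassigned"),
            " sample(s) unassigned: no hydrography and no usable front latitudes")
  region
}

#' Bin sampling depths into the survey's depth categories
#'
#' @param depth numeric depths in metres.
#' @return factor with levels `"0-15"`, `"45-75"`, `"90-125"`; depths outside
#'   the categories map to the nearest bin.
#' @export
depth_bin <- function(depth) {
  cut(depth, breaks = c(-Inf, 30, 82.5, Inf),
      labels = c("0-15", "45-75", "90-125"))
}
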