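# Marker matrices: individuals x sites bi-allelic observations plus a taxon
# map assigning individuals to species, with haploid (0/1), diploid
# co-dominant (0/1/2) and dominant-band (0/1 on diploids) encodings.

#' Bi-allelic marker matrix
#'
#' @param data integer matrix, individuals in rows (rownames are individual
#'   ids) and sites in columns.  Haploid data take values 0/1 (1 = red),
#'   diploid co-dominant data 0/1/2 (count of red alleles), dominant data
#'   0/1 (band presence; the red allele is dominant).  `NA` marks missing.
#' @param taxon_map named list: species name -> character vector of
#'   individual ids (must cover the rownames of `data`).
#' @param diploid logical; each individual carries two lineages.
#' @param dominant logical; band presence/absence of a dominant red allele
#'   (requires `diploid = TRUE`).
#' @param polymorphic_only logical flag recording that the data were
#'   ascertained to contain only polymorphic sites; [dataset_loglik()] then
#'   conditions the likelihood on polymorphism by default.
#' @return An object of class `"marker_matrix"`.
#' @export
marker_matrix <- function(data, taxon_map, diploid = FALSE, dominant = FALSE,
                          polymorphic_only = FALSE) {
  data <- as.matrix(data)
  if (dominant && !diploid)
    stop("dominant markers imply diploid individuals")
  inds <- unlist(taxon_map, use.names = FALSE)
  if (is.null(rownames(data)))
    stop("data must have individual ids as rownames")
  if (!setequal(rownames(data), inds))
    stop("taxon map individuals do not match the rownames of data")
  hi <- if (diploid && !dominant) 2L else 1L
  bad <- data[!is.na(data)]
  if (length(bad) && (any(bad < 0L) || any(bad > hi)))
    stop("marker values out of range 0..", hi)
  structure(list(data = data, taxon_map = taxon_map, diploid = diploid,
                 dominant = dominant, polymorphic_only = polymorphic_only),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("Marker matrix: %d individuals (%d species), %d sites; %s%s%s\n",
              nrow(x$data), length(x$taxon_map), ncol(x$data),
              if (x$diploid) "diploid" else "haploid",
              if (x$dominant) ", dominant bands" else "",
              if (x$polymorphic_only) ", polymorphic-only" else ""))
  invisible(x)
}

#' Number of sampled lineages per species and in total
#' @param mm a `"marker_matrix"`.
#' @return A list with `per_species` (named integer) and `M` (total).
#' @export
lineage_counts <- function(mm) {
  per <- vapply(mm$taxon_map, length, 1L) * (if (mm$diploid) 2L else 1L)
  list(per_species = per, M = sum(per))
}

# Per-site per-species observation table used by the likelihood: for every
# species, `count` (= n_x individuals for dominant data, lineage count
# otherwise), the observed red total `red`, and the number of missing
# individuals `miss`.  Dominant data with missing entries are not supported.
site_patterns <- function(mm) {
  sp <- names(mm$taxon_map)
  m <- ncol(mm$data)
  npat <- vector("list", m)
  for (i in seq_len(m)) {
    col <- mm$data[, i]
    tab <- lapply(sp, function(s) {
      v <- col[mm$taxon_map[[s]]]
      miss <- sum(is.na(v))
      if (mm$dominant) {
        if (miss > 0L) stop("missing entries are not supported for dominant markers")
        list(count = length(v), red = sum(v), miss = 0L, dominant = TRUE)
      } else if (mm$diploid) {
        list(count = 2L * length(v), red = sum(v, na.rm = TRUE),
             miss = 2L * miss, dominant = FALSE)
      } else {
        list(count = length(v), red = sum(v, na.rm = TRUE),
             miss = miss, dominant = FALSE)
      }
    })
    names(tab) <- sp
    npat[[i]] <- tab
  }
  npat
}

# Deduplicate site patterns; returns list(patterns, weights, key).
unique_patterns <- function(mm) {
  pats <- site_patterns(mm)
  keys <- vapply(pats, function(p)
    paste(vapply(p, function(x)
      sprintf("%d/%d/%d/%d", x$count, x$red, x$miss, as.integer(x$dominant)), ""),
      collapse = ";"), "")
  ord <- order(keys)
  ukeys <- unique(keys[ord])
  w <- as.numeric(table(keys)[ukeys])
  list(patterns = pats[match(ukeys, keys)], weights = w, key = ukeys)
}

#' Parse a taxon map string
#'
#' Accepts the `species: ind1,ind2; species2: ind3` form (angle brackets
#' allowed around the whole map).
#' @param text the map string.
#' @return Named list species -> individual ids.
#' @export
parse_taxon_map <- function(text) {
  s <- gsub("[<>]", "", text)
  parts <- strsplit(s, ";")[[1]]
  parts <- trimws(parts)
  parts <- parts[parts != ""]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, ":")[[1]]
    if (length(kv) != 2L) stop("malformed taxon map entry: ", p)
    out[[trimws(kv[1])]] <- trimws(strsplit(kv[2], ",")[[1]])
  }
  out
}

#' Read / write marker matrices as TSV
#'
#' Tab-separated, header row of site ids, one row per individual; values in
#' {0,1} (haploid / dominant band), {0,1,2} (diploid co-dominant), `?` for
#' missing.  The taxon map is given separately (string or file containing
#' `species: ind1,ind2; ...`).
#'
#' @param file path to the TSV.
#' @param taxon_map taxon map (named list or string accepted by
#'   [parse_taxon_map()]).
#' @param diploid,dominant,polymorphic_only encoding flags, as in
#'   [marker_matrix()].
#' @return A `"marker_matrix"`.
#' @export
read_marker_tsv <- function(file, taxon_map, diploid = FALSE,
                            dominant = FALSE, polymorphic_only = FALSE) {
  if (is.character(taxon_map)) taxon_map <- parse_taxon_map(taxon_map)
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           row.names = 1, colClasses = "character",
                           check.names = FALSE)
  m <- as.matrix(tab)
  m[m == "?"] <- NA
  storage.mode(m) <- "integer"
  marker_matrix(m, taxon_map, diploid = diploid, dominant = dominant,
                polymorphic_only = polymorphic_only)
}

#' @rdname read_marker_tsv
#' @param mm a `"marker_matrix"` to write.
#' @export
write_marker_tsv <- function(mm, file) {
  m <- mm$data
  storage.mode(m) <- "character"
  m[is.na(m)] <- "?"
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  utils::write.table(m, file, sep = "\t", quote = FALSE, col.names = NA)
  invisible(file)
}
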