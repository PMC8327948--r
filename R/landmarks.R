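#' Landmark dataset container
#'
#' Bundles 3D landmark configurations for a set of specimens together with
#' the wild/domestic group factor and a pair identifier. Coordinates are held
#' as an `n x p x 3` array in consistent (arbitrary) length units. Landmark
#' indexing is 0-free and 1-based inside R; files written by the package use
#' 1-based landmark numbers as well.
#'
#' @param coords numeric array `n x p x 3` (specimens x landmarks x xyz), or
#'   a list of `p x 3` matrices of equal dimension.
#' @param group character/factor of length `n` with levels `"wild"` and/or
#'   `"domestic"`.
#' @param specimen_ids optional character ids (default `spec_1..n`).
#' @param pair_id single string naming the wild/domestic pair.
#' @param landmark_names optional character of length `p`.
#' @return An object of class `landmark_dataset` with elements `coords`,
#'   `group`, `specimen_ids`, `pair_id`, `landmark_names`.
#' @examples
#' a <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
#' d <- landmark_dataset(a, group = c("wild", "domestic"), pair_id = "toy")
#' dim(d$coords)
#' @export
landmark_dataset <- function(coords, group, specimen_ids = NULL,
                             pair_id = "pair", landmark_names = NULL) {
  if (is.list(coords)) {
    p <- unique(vapply(coords, nrow, integer(1)))
    if (length(p) != 1L)
      stop("inconsistent landmark count across specimens: ",
           paste(sort(p), collapse = ", "))
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("'coords' must be an n x p x 3 array")
  dimnames(coords) <- NULL
  n <- dim(coords)[1]; p <- dim(coords)[2]
  if (is.null(specimen_ids)) specimen_ids <- paste0("spec_", seq_len(n))
  if (is.null(landmark_names)) landmark_names <- paste0("LM", seq_len(p))
  group <- as.character(group)
  if (length(group) != n)
    stop("'group' must have one label per specimen")
  bad_grp <- setdiff(unique(group), c("wild", "domestic"))
  if (length(bad_grp))
    stop("group labels must be 'wild' or 'domestic'; found: ",
         paste(bad_grp, collapse = ", "))
  if (anyNA(coords) || any(!is.finite(coords))) {
    bad <- which(apply(coords, 1, function(m) any(!is.finite(m))))
    stop("non-finite coordinates for specimen(s): ",
         paste(specimen_ids[bad], collapse = ", "),
         " (landmark ",
         paste(unique(which(!is.finite(coords), arr.ind = TRUE)[, 2]),
               collapse = ","), ")")
  }
  structure(list(coords = coords, group = group,
                 specimen_ids = as.character(specimen_ids),
                 pair_id = pair_id,
                 landmark_names = as.character(landmark_names)),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  tab <- table(factor(x$group, levels = c("wild", "domestic")))
  cat(sprintf("landmark_dataset '%s': %d specimens (%d wild / %d domestic), %d landmarks x 3D\n",
              x$pair_id, dim(x$coords)[1], tab["wild"], tab["domestic"],
              dim(x$coords)[2]))
  invisible(x)
}

n_specimens <- function(x) dim(x$coords)[1]
n_landmarks <- function(x) dim(x$coords)[2]

#' A-priori landmark module map
#'
#' Assigns every landmark to exactly one of the two embryonic-tissue modules:
#' neural crest (`NC`) or mesoderm (`MD`).
#'
#' @param assignment character of length `p` with values `"NC"` / `"MD"`.
#' @return `module_map` object with `assignment` and `counts` (named c(NC, MD)).
#' @examples
#' module_map(c("NC", "NC", "MD", "MD"))$counts
#' @export
module_map <- function(assignment) {
  assignment <- as.character(assignment)
  bad <- setdiff(unique(assignment), c("NC", "MD"))
  if (length(bad))
    stop("invalid module label(s): ", paste(bad, collapse = ", "),
         "; valid labels are 'NC' and 'MD'")
  counts <- c(NC = sum(assignment == "NC"), MD = sum(assignment == "MD"))
  if (any(counts == 0L))
    stop("both modules must be non-empty (got NC=", counts["NC"],
         ", MD=", counts["MD"], ")")
  structure(list(assignment = assignment, counts = counts),
            class = "module_map")
}

#' Bilateral symmetry pairing
#'
#' Records which landmarks are left/right counterparts and which lie on the
#' midline (sagittal plane). Indices are 1-based, must be disjoint and must
#' jointly cover all `p` landmarks.
#'
#' @param pairs integer matrix with columns `left`, `right` (may have 0 rows).
#' @param midline integer vector of unpaired landmark indices.
#' @param p total number of landmarks.
#' @return `symmetry_pairing` object.
#' @export
symmetry_pairing <- function(pairs, midline = integer(0), p) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("left", "right")))
  midline <- as.integer(midline)
  all_idx <- c(pairs, midline)
  if (anyDuplicated(all_idx))
    stop("landmark index appears in more than one pairing role")
  if (!setequal(all_idx, seq_len(p)))
    stop("pairing must cover all ", p, " landmarks exactly once; got ",
         length(all_idx), " indices")
  structure(list(pairs = pairs, midline = midline, p = as.integer(p)),
            class = "symmetry_pairing")
}

flatten_coords <- function(coords) {
  # n x p x 3 -> n x 3p with columns x1,y1,z1,x2,...
  n <- dim(coords)[1]; p <- dim(coords)[2]
  out <- matrix(aperm(coords, c(3, 2, 1)), nrow = n, byrow = TRUE)
  colnames(out) <- paste0(rep(paste0("LM", seq_len(p)), each = 3),
                          "_", c("x", "y", "z"))
  out
}

unflatten_coords <- function(mat) {
  n <- nrow(mat); p <- ncol(mat) / 3L
  aperm(array(t(mat), c(3, p, n)), c(3, 2, 1))
}

module_columns <- function(map, which) {
  idx <- which(map$assignment == which)
  as.vector(vapply(idx, function(j) 3L * (j - 1L) + 1:3, integer(3)))
}

#' Read landmark data from file
#'
#' Supported dialects: `csv-wide` (one row per specimen, columns
#' `LM<i>_x, LM<i>_y, LM<i>_z`, plus `specimen_id` and `group`), `csv-long`
#' (columns `specimen_id, group, landmark, x, y, z`), and `tps` (records of
#' `LM3=<p>` blocks with `ID=` lines; group taken from an `ID=<id>__<group>`
#' suffix convention or defaults to `"wild"`).
#'
#' @param path file path.
#' @param dialect one of `"csv-wide"`, `"csv-long"`, `"tps"`.
#' @param pair_id pair identifier stored on the dataset.
#' @return [landmark_dataset()]
#' @export
read_landmarks <- function(path, dialect = c("csv-wide", "csv-long", "tps"),
                           pair_id = "pair") {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- match.arg(dialect)
  switch(dialect,
         "csv-wide" = read_landmarks_wide(path, pair_id),
         "csv-long" = read_landmarks_long(path, pair_id),
         "tps"      = read_landmarks_tps(path, pair_id))
}

read_landmarks_wide <- function(path, pair_id) {
  df <- utils::read.csv(path, check.names = FALSE)
  coord_cols <- grep("^LM[0-9]+_[xyz]$", names(df), value = TRUE)
  p <- length(coord_cols) / 3L
  if (p < 1 || p != round(p))
    stop("csv-wide file must contain complete LM<i>_x/y/z triplets")
  ord <- paste0(rep(paste0("LM", seq_len(p)), each = 3), "_", c("x", "y", "z"))
  if (!all(ord %in% coord_cols))
    stop("incomplete coordinate triplet: missing ",
         paste(setdiff(ord, coord_cols), collapse = ", "))
  m <- as.matrix(df[, ord])
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))
    stop("missing coordinate(s) for specimen ",
         paste(df$specimen_id[bad], collapse = ", "))
  }
  landmark_dataset(unflatten_coords(m), group = df$group,
                   specimen_ids = df$specimen_id, pair_id = pair_id)
}

read_landmarks_long <- function(path, pair_id) {
  df <- utils::read.csv(path)
  need <- c("specimen_id", "landmark", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("csv-long file must have columns ", paste(need, collapse = ", "))
  ids <- unique(df$specimen_id)
  p <- length(unique(df$landmark))
  cfgs <- lapply(ids, function(id) {
    sub <- df[df$specimen_id == id, ]
    sub <- sub[order(sub$landmark), ]
    if (nrow(sub) != p)
      stop("specimen ", id, " has ", nrow(sub), " landmarks, expected ", p)
    if (anyNA(sub[, c("x", "y", "z")]))
      stop("missing coordinate for specimen ", id, " at landmark ",
           paste(sub$landmark[apply(is.na(sub[, c("x", "y", "z")]), 1, any)],
                 collapse = ","))
    as.matrix(sub[, c("x", "y", "z")])
  })
  grp <- vapply(ids, function(id) df$group[df$specimen_id == id][1],
                character(1))
  landmark_dataset(cfgs, group = grp, specimen_ids = ids, pair_id = pair_id)
}

read_landmarks_tps <- function(path, pair_id) {
  lines <- readLines(path)
  lm_at <- grep("^LM3?=", lines)
  if (!length(lm_at)) stop("no LM= records found in tps file: ", path)
  cfgs <- list(); ids <- character(0); grp <- character(0)
  for (k in seq_along(lm_at)) {
    start <- lm_at[k]
    p <- as.integer(sub("^LM3?=", "", lines[start]))
    block <- lines[(start + 1):(start + p)]
    xyz <- t(vapply(strsplit(trimws(block), "[ \t]+"),
                    function(v) as.numeric(v[1:3]), numeric(3)))
    if (anyNA(xyz))
      stop("missing coordinate in tps record ", k, " (specimen block at line ",
           start, ")")
    end <- if (k < length(lm_at)) lm_at[k + 1] - 1 else length(lines)
    idline <- grep("^ID=", lines[(start + p):end], value = TRUE)
    id <- if (length(idline)) sub("^ID=", "", idline[1]) else paste0("spec_", k)
    g <- if (grepl("__domestic$", id)) "domestic"
         else if (grepl("__wild$", id)) "wild" else "wild"
    id <- sub("__(wild|domestic)$", "", id)
    cfgs[[k]] <- xyz; ids <- c(ids, id); grp <- c(grp, g)
  }
  landmark_dataset(cfgs, group = grp, specimen_ids = ids, pair_id = pair_id)
}

#' Write landmark data
#'
#' @param dataset a [landmark_dataset()].
#' @param path output file.
#' @param dialect `"csv-wide"` or `"csv-long"` (tps is read-only).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(dataset, path, dialect = c("csv-wide", "csv-long")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv-wide") {
    m <- flatten_coords(dataset$coords)
    df <- data.frame(specimen_id = dataset$specimen_ids,
                     group = dataset$group, m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    n <- n_specimens(dataset); p <- n_landmarks(dataset)
    df <- data.frame(
      specimen_id = rep(dataset$specimen_ids, each = p),
      group = rep(dataset$group, each = p),
      landmark = rep(seq_len(p), times = n),
      x = as.vector(t(dataset$coords[, , 1])),
      y = as.vector(t(dataset$coords[, , 2])),
      z = as.vector(t(dataset$coords[, , 3])))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a landmark-to-module map
#'
#' Two-column CSV `landmark,module` with 1-based landmark numbers covering
#' every landmark of `dataset` exactly once and labels in NC/MD.
#'
#' @param path CSV file.
#' @param dataset dataset the map must align with.
#' @return [module_map()]
#' @export
read_module_map <- function(path, dataset) {
  df <- utils::read.csv(path)
  p <- n_landmarks(dataset)
  if (anyDuplicated(df$landmark))
    stop("duplicated landmark in module map: ",
         paste(df$landmark[duplicated(df$landmark)], collapse = ","))
  if (!setequal(df$landmark, seq_len(p)))
    stop("module map must assign each of the ", p,
         " landmarks exactly once; missing: ",
         paste(setdiff(seq_len(p), df$landmark), collapse = ","))
  module_map(df$module[order(df$landmark)])
}

#' Write a module map as two-column CSV
#' @param map a [module_map()].
#' @param path output file.
#' @export
write_module_map <- function(map, path) {
  utils::write.csv(data.frame(landmark = seq_along(map$assignment),
                              module = map$assignment),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a bilateral pairing table
#'
#' CSV with columns `landmark,partner`; `partner = 0` marks a midline
#' landmark, otherwise the row gives one direction of a left/right pair
#' (the reciprocal row must be present and consistent).
#'
#' @param path CSV file.
#' @param dataset dataset the pairing must cover.
#' @return [symmetry_pairing()]
#' @export
read_symmetry_pairing <- function(path, dataset) {
  df <- utils::read.csv(path)
  p <- n_landmarks(dataset)
  midline <- df$landmark[df$partner == 0]
  paired <- df[df$partner != 0, ]
  seen <- logical(p); prs <- NULL
  for (i in seq_len(nrow(paired))) {
    a <- paired$landmark[i]; b <- paired$partner[i]
    if (df$partner[df$landmark == b] != a)
      stop("pairing not reciprocal for landmarks ", a, " and ", b)
    if (!seen[a] && !seen[b]) {
      prs <- rbind(prs, c(min(a, b), max(a, b)))
      seen[c(a, b)] <- TRUE
    }
  }
  symmetry_pairing(prs, midline, p)
}

#' Write a bilateral pairing table
#' @param pairing a [symmetry_pairing()].
#' @param path output file.
#' @export
write_symmetry_pairing <- function(pairing, path) {
  p <- pairing$p
  partner <- integer(p)
  partner[pairing$pairs[, 1]] <- pairing$pairs[, 2]
  partner[pairing$pairs[, 2]] <- pairing$pairs[, 1]
  utils::write.csv(data.frame(landmark = seq_len(p), partner = partner),
                   path, row.names = FALSE)
  invisible(path)
}

#' Split a pair dataset into its wild and domestic subsets
#'
#' @param dataset a [landmark_dataset()] containing both groups.
#' @return list with elements `wild` and `domestic`, each a dataset.
#' @export
split_pair <- function(dataset) {
  for (g in c("wild", "domestic"))
    if (!any(dataset$group == g))
      stop("group '", g, "' absent from dataset '", dataset$pair_id, "'")
  subset_ds <- function(keep)
    landmark_dataset(dataset$coords[keep, , , drop = FALSE],
                     group = dataset$group[keep],
                     specimen_ids = dataset$specimen_ids[keep],
                     pair_id = dataset$pair_id,
                     landmark_names = dataset$landmark_names)
  list(wild = subset_ds(dataset$group == "wild"),
       domestic = subset_ds(dataset$group == "domestic"))
}
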