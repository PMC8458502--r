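# Monoisotopic masses of the most abundant isotope (IUPAC 2021 values).
.MONO_MASS <- c(
    C = 12.0,
    H = 1.00782503207,
    N = 14.0030740048,
    O = 15.9949146196,
    S = 31.97207100,
    P = 30.97376163,
    Cl = 34.96885268,
    F = 18.99840322,
    Br = 78.9183371,
    I = 126.904473,
    Na = 22.9897692809,
    K = 38.96370668,
    Si = 27.9769265325,
    Se = 79.9165213
)

.PROTON_MASS <- 1.00727646

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-style formula (element symbols followed by optional counts,
#' e.g. `"C11H12N2O3"`) and sums monoisotopic atomic masses.
#'
#' @param formula character(1) elemental formula
#' @return monoisotopic neutral mass in Da
#' @examples
#' monoisotopicMass("C11H12N2O3")  # 220.0848
#' @export
monoisotopicMass <- function(formula) {
    stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
    if (sum(nchar(tokens)) != nchar(formula))
        stop("cannot parse formula: ", formula)
    elements <- sub("[0-9]*$", "", tokens)
    counts <- as.integer(sub("^[A-Z][a-z]?", "", paste0(tokens, "")))
    counts[is.na(counts)] <- 1L
    unknown <- setdiff(elements, names(.MONO_MASS))
    if (length(unknown))
        stop("unknown element symbol: ", paste(unknown, collapse = ", "))
    sum(.MONO_MASS[elements] * counts)
}

#' Theoretical adduct m/z
#'
#' Computes the m/z of the protonated (`[M+H]+`) or deprotonated
#' (`[M-H]-`) ion of a neutral formula: the monoisotopic mass plus or
#' minus one proton mass (1.00727646 Da).
#'
#' @param formula character(1) elemental formula of the neutral compound
#' @param adduct `"[M+H]+"` or `"[M-H]-"`
#' @return m/z in Da
#' @examples
#' adductMz("C10H16N2O2", "[M+H]+")  # 197.1285
#' adductMz("C11H12N2O3", "[M+H]+")  # 221.0921
#' @export
adductMz <- function(formula, adduct = c("[M+H]+", "[M-H]-")) {
    adduct <- match.arg(adduct)
    m <- monoisotopicMass(formula)
    if (adduct == "[M+H]+") m + .PROTON_MASS else m - .PROTON_MASS
}

#' Match a measured feature against a compound library
#'
#' A library compound matches when the relative deviation between the
#' observed m/z and the theoretical adduct m/z (protonated for
#' positive-mode features, deprotonated for negative) is at most
#' `ppm_tolerance` parts per million (inclusive at the boundary).  Matches
#' are ranked by absolute ppm error, ties broken by compound id.
#'
#' @param mz observed m/z (Da)
#' @param ion_mode `"positive"` or `"negative"`
#' @param library data.frame with columns `compound_id`, `name`, `formula`,
#'   and optionally precomputed `monoisotopic_mass`
#' @param ppm_tolerance tolerance in ppm (default 10)
#' @return data.frame of matches (possibly empty) with `compound_id`,
#'   `name`, `formula`, `theoretical_mz`, `ppm`, ordered best-first
#' @export
libraryMatch <- function(mz, ion_mode, library, ppm_tolerance = 10) {
    stopifnot(is.numeric(mz), length(mz) == 1L, mz > 0)
    ion_mode <- match.arg(ion_mode, c("positive", "negative"))
    if (is.null(library) || nrow(library) == 0L)
        stop("compound library is empty")
    mono <- library$monoisotopic_mass
    if (is.null(mono))
        mono <- vapply(library$formula, monoisotopicMass, numeric(1))
    theo <- if (ion_mode == "positive") mono + .PROTON_MASS else mono - .PROTON_MASS
    ppm <- (mz - theo) / theo * 1e6
    # inclusive boundary, with a 1e-9 ppm guard against round-off at it
    keep <- abs(ppm) <= ppm_tolerance + 1e-9
    out <- data.frame(compound_id = library$compound_id[keep],
                      name = library$name[keep],
                      formula = library$formula[keep],
                      theoretical_mz = theo[keep],
                      ppm = ppm[keep],
                      stringsAsFactors = FALSE)
    out[order(abs(out$ppm), out$compound_id), , drop = FALSE]
}

#' Assign an MSI identification level from evidence flags
#'
#' Applies the highest-evidence rule of the Metabolomics Standards
#' Initiative bookkeeping: an in-house authentic-standard spectral match
#' gives level 1; otherwise a public spectral-library match level 2;
#' otherwise an in-silico structure annotation level 3; otherwise a
#' chemical-class-only annotation level 4; otherwise a bare sum formula
#' `"formula_only"`; with no evidence at all, `"unknown"`.
#'
#' @param inhouse_spectral,public_spectral,in_silico_structure,class_only,formula_only
#'   logical evidence flags (vectorised; recycled to a common length)
#' @return character vector of levels in
#'   `c("1","2","3","4","formula_only","unknown")`
#' @examples
#' assignMsiLevel(inhouse_spectral = TRUE, public_spectral = TRUE)  # "1"
#' @export
assignMsiLevel <- function(inhouse_spectral = FALSE, public_spectral = FALSE,
                           in_silico_structure = FALSE, class_only = FALSE,
                           formula_only = FALSE) {
    n <- max(length(inhouse_spectral), length(public_spectral),
             length(in_silico_structure), length(class_only),
             length(formula_only))
    f <- function(x) rep_len(as.logical(x), n)
    ifelse(f(inhouse_spectral), "1",
    ifelse(f(public_spectral), "2",
    ifelse(f(in_silico_structure), "3",
    ifelse(f(class_only), "4",
    ifelse(f(formula_only), "formula_only", "unknown")))))
}

#' Compound-class enrichment of selected features
#'
#' Compares the class composition of a selected feature set against the
#' full background set with one 2x2 Fisher exact test per class.  The 2x2
#' table for a class counts selected-in-class, selected-not-in-class,
#' rest-in-class, rest-not-in-class, where "rest" is the background minus
#' the selected set.  A class is called enriched only when the Fisher p is
#' below `alpha` (no multiple-testing correction -- a single conservative
#' alpha is used instead, as in the workflow this package implements) AND
#' the selected-set class fraction exceeds the background fraction
#' (`difference > 0`); classes that are depleted are never flagged however
#' small their p.
#'
#' @param selected character vector of class labels of the selected
#'   features (a multiset: one entry per selected feature)
#' @param background character vector of class labels of the full
#'   background set (must contain the selected set)
#' @param alpha significance threshold (default 0.005)
#' @param alternative `"two.sided"` (default) or `"greater"` for the
#'   one-sided hypergeometric tail
#' @return data.frame sorted by p with columns `class`, `a`, `b`, `c`, `d`,
#'   `fisher_p`, `difference`, `enriched`
#' @export
classEnrichment <- function(selected, background, alpha = 0.005,
                            alternative = c("two.sided", "greater")) {
    alternative <- match.arg(alternative)
    if (length(selected) == 0L)
        stop("selected set is empty")
    selected <- as.character(selected)
    background <- as.character(background)
    n_sel <- length(selected)
    n_bg <- length(background)
    if (n_sel > n_bg)
        stop("selected set larger than background universe")
    classes <- sort(unique(background))
    res <- lapply(classes, function(cl) {
        a <- sum(selected == cl)
        b <- n_sel - a
        tot <- sum(background == cl)
        cc <- tot - a              # rest of background, in class
        d <- (n_bg - n_sel) - cc
        p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L),
                                alternative = alternative)$p.value
        diff <- a / n_sel - tot / n_bg
        data.frame(class = cl, a = a, b = b, c = cc, d = d,
                   fisher_p = p, difference = diff,
                   enriched = p < alpha & diff > 0,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res[order(res$fisher_p, res$class), , drop = FALSE]
}

#' Default ontology-branch removal list
#'
#' The branches dropped before functional-semantic aggregation: drug
#' classification schemes, exposure/disposition bookkeeping, and
#' superclasses that carry no chemical entities of their own.
#'
#' @return character vector of root-anchored branch prefixes
#' @export
defaultOntologyRemovalList <- function() {
    c("Target-based classification of drugs",
      "Anatomical Therapeutic Chemical",
      "Major components of natural products",
      "Disposition/Pathways/SMP",
      "Disposition/Pathways/map",
      "Disposition/Source",
      "Process",
      "Physiological effect",
      "Disposition/Route of exposure",
      "Disposition/Cellular Location",
      "Disposition",
      "Taxonomy",
      "Metabolic pathways",
      "Role",
      "Role/Industrial application",
      "Role/Industrial application/Pharmaceutical industry",
      "Biological location/Biofluid and excreta",
      "Biological location/Subcellular")
}

.normalizePath1 <- function(path) {
    parts <- strsplit(path, "/", fixed = TRUE)[[1]]
    parts <- trimws(gsub("[[:space:]]+", " ", parts))
    if (any(!nzchar(parts)))
        stop("malformed ontology path: '", path, "'")
    # Sentence-case each term so "blood" and "Blood" collapse.
    parts <- paste0(toupper(substring(parts, 1L, 1L)),
                    tolower(substring(parts, 2L)))
    paste(parts, collapse = "/")
}

#' Prune and merge multi-source ontology paths
#'
#' Ontology paths gathered from several sources are case- and
#' whitespace-normalised (so `"Blood"` and `"blood"` collapse), duplicate
#' paths per compound are dropped, and any path equal to or descending from
#' an entry of the removal list is removed.  Removal-list entries are
#' normalised with the same rule before matching.
#'
#' @param paths data.frame with columns `compound_id` and `path`
#'   (root-anchored, `/`-separated), optionally `source`
#' @param removal_list branch prefixes to drop
#'   (default [defaultOntologyRemovalList()])
#' @return data.frame with columns `compound_id`, `path` -- normalised,
#'   deduplicated, pruned
#' @export
pruneOntology <- function(paths, removal_list = defaultOntologyRemovalList()) {
    stopifnot(is.data.frame(paths), all(c("compound_id", "path") %in% colnames(paths)))
    if (nrow(paths) == 0L)
        return(data.frame(compound_id = character(), path = character(),
                          stringsAsFactors = FALSE))
    norm <- vapply(paths$path, .normalizePath1, character(1), USE.NAMES = FALSE)
    rem <- vapply(removal_list, .normalizePath1, character(1), USE.NAMES = FALSE)
    drop <- rep(FALSE, length(norm))
    for (r in rem)
        drop <- drop | norm == r | startsWith(norm, paste0(r, "/"))
    out <- data.frame(compound_id = as.character(paths$compound_id)[!drop],
                      path = norm[!drop], stringsAsFactors = FALSE)
    unique(out)
}

#' Aggregate pruned ontology paths into treemap counts
#'
#' For every term appearing at any depth of the pruned paths, counts the
#' number of distinct compounds carrying that term either directly or on
#' any descendant path, so parent counts are the size of the distinct union
#' of their own and their descendants' compounds (hence monotone
#' non-increasing with depth).
#'
#' @param paths data.frame with columns `compound_id`, `path` (as returned
#'   by [pruneOntology()])
#' @return data.frame with columns `term` (full root-anchored term path),
#'   `level` (depth, 1 = root), `count` (distinct compounds), sorted by
#'   term
#' @export
aggregateTreemap <- function(paths) {
    if (nrow(paths) == 0L)
        return(data.frame(term = character(), level = integer(),
                          count = integer(), stringsAsFactors = FALSE))
    expand <- lapply(seq_len(nrow(paths)), function(i) {
        parts <- strsplit(paths$path[i], "/", fixed = TRUE)[[1]]
        pref <- vapply(seq_along(parts),
                       function(k) paste(parts[seq_len(k)], collapse = "/"),
                       character(1))
        data.frame(compound_id = paths$compound_id[i], term = pref,
                   level = seq_along(parts), stringsAsFactors = FALSE)
    })
    expand <- unique(do.call(rbind, expand))
    agg <- stats::aggregate(compound_id ~ term + level, data = expand,
                            FUN = function(x) length(unique(x)))
    names(agg)[names(agg) == "compound_id"] <- "count"
    agg <- agg[order(agg$term), , drop = FALSE]
    rownames(agg) <- NULL
    agg
}

#' Annotate selected features
#'
#' Convenience wrapper combining [libraryMatch()] per feature with MSI
#' bookkeeping and the per-feature regression direction: for every feature
#' in `features`, the best library match within the ppm tolerance (if any)
#' is reported together with the match error and the assigned MSI level
#' (level 2 for a library mass match here -- a mass-only match against a
#' public library is not authentic-standard evidence).
#'
#' @param features data.frame with columns `feature_id`, `ion_mode`, `mz`
#' @param library compound library as in [libraryMatch()]
#' @param regressions optional data.frame from [perFeatureRegression()]
#'   whose `slope`/`p_value`/`direction` are joined by `feature_id`
#' @param ppm_tolerance tolerance in ppm
#' @return data.frame, one row per feature: `feature_id`, `putative_name`,
#'   `formula`, `library_match_ppm`, `msi_level`, plus regression columns
#'   when supplied
#' @export
annotateFeatures <- function(features, library, regressions = NULL,
                             ppm_tolerance = 10) {
    rows <- lapply(seq_len(nrow(features)), function(i) {
        hits <- libraryMatch(features$mz[i], features$ion_mode[i], library,
                             ppm_tolerance)
        if (nrow(hits)) {
            data.frame(feature_id = features$feature_id[i],
                       putative_name = hits$name[1L],
                       formula = hits$formula[1L],
                       library_match_ppm = hits$ppm[1L],
                       msi_level = "2", stringsAsFactors = FALSE)
        } else {
            data.frame(feature_id = features$feature_id[i],
                       putative_name = "", formula = "",
                       library_match_ppm = NA_real_,
                       msi_level = "unknown", stringsAsFactors = FALSE)
        }
    })
    out <- do.call(rbind, rows)
    if (!is.null(regressions)) {
        idx <- match(out$feature_id, regressions$feature_id)
        out$slope <- regressions$slope[idx]
        out$p_value <- regressions$p_value[idx]
        out$direction <- regressions$direction[idx]
    }
    out
}
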