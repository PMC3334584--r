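# Fixed lineage-level species scaffold for placing ancient duplications.

#' Lineage names recognized by the scaffold
#'
#' The seven major flowering-plant lineages used throughout the package, in
#' phylogenetic depth order (earliest-diverging first). Core eudicots are
#' caryophyllids + asterids + rosids; basal eudicots (Ranunculales and allies)
#' diverge earlier.
#'
#' @return Character vector of the seven lineage names.
#' @export
lineages <- function() {
  c("basal_angiosperm", "magnoliid", "monocot", "basal_eudicot",
    "caryophyllid", "asterid", "rosid")
}

# depth rank used for outgroup priority and deepest-inside-lineage precedence;
# caryophyllids and asterids are interchangeable core-eudicot evidence
.lineage_depth <- c(
  basal_angiosperm = 1, magnoliid = 2, monocot = 3, basal_eudicot = 4,
  caryophyllid = 5, asterid = 5, rosid = 6
)

#' Normalize a species label
#'
#' Lowercases, trims, and collapses whitespace/underscores so that
#' \code{"Oryza_sativa"} and \code{"oryza sativa"} resolve identically.
#'
#' @param x character vector of species labels.
#' @return normalized character vector.
#' @export
normalize_species <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]_]+", " ", x)
}

#' Build the default species-to-lineage panel
#'
#' Covers the eight sequenced genomes and the transcriptome species panel
#' (basal angiosperms, magnoliids, non-grass monocots plus the two grasses,
#' basal eudicots, caryophyllids, asterids, rosids) used to populate
#' orthogroups. Grass monocots are flagged so classification can optionally
#' exclude them as duplication evidence.
#'
#' @return An object of class \code{lineage_panel}.
#' @export
build_default_panel <- function() {
  map <- c(
    # sequenced genomes
    "Arabidopsis thaliana" = "rosid",
    "Carica papaya" = "rosid",
    "Cucumis sativus" = "rosid",
    "Populus trichocarpa" = "rosid",
    "Glycine max" = "rosid",
    "Vitis vinifera" = "rosid",
    "Oryza sativa" = "monocot",
    "Sorghum bicolor" = "monocot",
    # asterids
    "Panax quinquefolius" = "asterid",
    "Lindenbergia phillipensis" = "asterid",
    "Helianthus annuus" = "asterid",
    "Solanum tuberosum" = "asterid",
    "Mimulus gutatus" = "asterid",
    # basal eudicots
    "Papaver somniferum" = "basal_eudicot",
    "Papaver setigerum" = "basal_eudicot",
    "Papaver rhoeas" = "basal_eudicot",
    "Papaver bracteatum" = "basal_eudicot",
    "Eschscholzia californica" = "basal_eudicot",
    "Argemone mexicana" = "basal_eudicot",
    "Akebia trifoliata" = "basal_eudicot",
    "Podophyllum pelatum" = "basal_eudicot",
    "Platanus occidentalis" = "basal_eudicot",
    "Aquilegia formosa" = "basal_eudicot",
    "Aquilegia pubescens" = "basal_eudicot",
    # caryophyllids
    "Mesembryanthemum crystallinum" = "caryophyllid",
    "Beta vulgaris" = "caryophyllid",
    # monocots (non-grass)
    "Acorus americanus" = "monocot",
    "Chamaedorea seifrizii" = "monocot",
    "Chlorophytum rhizopendulum" = "monocot",
    "Neoregelia sp." = "monocot",
    "Typha angustifolia" = "monocot",
    # magnoliids
    "Persea americana" = "magnoliid",
    "Aristolochia fimbriata" = "magnoliid",
    "Liriodendron tulipifera" = "magnoliid",
    # basal angiosperms
    "Nuphar advena" = "basal_angiosperm",
    "Amborella trichopoda" = "basal_angiosperm"
  )
  new_lineage_panel(map, grasses = c("Oryza sativa", "Sorghum bicolor"))
}

#' Construct a lineage panel from a species-to-lineage map
#'
#' @param map named character vector: names are species, values are lineage
#'   names (see \code{\link{lineages}}).
#' @param grasses character vector of species to flag as grass monocots.
#' @return \code{lineage_panel} object.
#' @export
new_lineage_panel <- function(map, grasses = character()) {
  if (is.null(names(map)) || any(!nzchar(names(map))))
    stop("panel map must be a named character vector of species")
  bad <- setdiff(unique(unname(map)), lineages())
  if (length(bad))
    stop("unknown lineage value(s): ", paste(bad, collapse = ", "))
  keys <- normalize_species(names(map))
  if (anyDuplicated(keys))
    stop("duplicate species after normalization: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  lk <- unname(map)
  names(lk) <- keys
  structure(list(map = lk, grasses = normalize_species(grasses)),
            class = "lineage_panel")
}

#' Read a lineage panel from a 2-column tab-separated file
#'
#' Expected columns: species, lineage. Lines starting with \code{#} and a
#' header row (first field \code{species}) are skipped. CRLF tolerated.
#'
#' @param path path to the TSV file.
#' @return \code{lineage_panel} object.
#' @export
read_panel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) && grepl("^species\\b", tolower(lines[1])))
    lines <- lines[-1]
  if (!length(lines)) stop("empty panel file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld < 2))
    stop("panel row ", which(nfld < 2)[1], " has fewer than 2 fields")
  map <- vapply(parts, function(p) trimws(p[2]), "")
  names(map) <- vapply(parts, function(p) trimws(p[1]), "")
  new_lineage_panel(map)
}

#' Write a lineage panel to a 2-column tab-separated file
#'
#' @param panel \code{lineage_panel}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "lineage_panel"))
  writeLines(paste(names(panel$map), unname(panel$map), sep = "\t"), path)
  invisible(path)
}

#' Look up the lineage of a species
#'
#' @param species species label (normalization is applied; see
#'   \code{\link{normalize_species}}).
#' @param panel \code{lineage_panel}.
#' @return lineage name (length-1 character).
#' @export
lineage_of <- function(species, panel) {
  stopifnot(inherits(panel, "lineage_panel"))
  key <- normalize_species(species)
  if (length(key) != 1 || !nzchar(key))
    stop("empty or invalid species label")
  hit <- panel$map[key]
  if (is.na(hit))
    stop("species not in lineage panel: '", species, "'")
  unname(hit)
}

#' Is a species a grass monocot?
#'
#' Grasses (e.g. rice, sorghum) have elevated substitution rates; the
#' classifier can be told to ignore them as duplication evidence.
#'
#' @param species species label.
#' @param panel \code{lineage_panel}.
#' @return logical.
#' @export
is_grass <- function(species, panel) {
  normalize_species(species) %in% panel$grasses
}

#' @export
print.lineage_panel <- function(x, ...) {
  cat("<lineage_panel>", length(x$map), "species,",
      length(unique(x$map)), "lineages\n")
  invisible(x)
}

#' Build the default species scaffold
#'
#' The fixed rooted lineage-level tree
#' \code{(basal_angiosperm,(magnoliid,(monocot,(basal_eudicot,(caryophyllid,asterid,rosid)))))},
#' with the relationships among the three core-eudicot lineages treated as an
#' unresolved trichotomy (the placement rule never needs to resolve it), and
#' the four candidate duplication branches:
#' \describe{
#'   \item{BR1}{subtends monocots + eudicots (duplication before the
#'     monocot/eudicot split).}
#'   \item{BR2}{subtends all eudicots (eudicot-wide duplication).}
#'   \item{BR3}{subtends core eudicots only (core eudicot-wide duplication).}
#'   \item{BR4}{subtends rosids only (rosid-wide duplication).}
#' }
#'
#' @param focal_species focal genome whose paralog pairs are classified;
#'   defaults to grape vine.
#' @return An object of class \code{species_scaffold} with elements
#'   \code{tree} (ape \code{phylo} over lineage labels), \code{branches}
#'   (list BR1--BR4 of subtended lineage sets), \code{focal_species},
#'   \code{focal_lineage}.
#' @export
build_default_scaffold <- function(focal_species = "Vitis vinifera") {
  nwk <- paste0("(basal_angiosperm,(magnoliid,(monocot,(basal_eudicot,",
                "(caryophyllid,asterid,rosid)))));")
  tree <- ape::read.tree(text = nwk)
  branches <- list(
    BR1 = c("monocot", "basal_eudicot", "caryophyllid", "asterid", "rosid"),
    BR2 = c("basal_eudicot", "caryophyllid", "asterid", "rosid"),
    BR3 = c("caryophyllid", "asterid", "rosid"),
    BR4 = "rosid"
  )
  structure(list(tree = tree, branches = branches,
                 focal_species = focal_species, focal_lineage = "rosid"),
            class = "species_scaffold")
}

#' Lineages subtended by a candidate duplication branch
#'
#' @param scaffold \code{species_scaffold}.
#' @param br one of \code{"BR1"}, \code{"BR2"}, \code{"BR3"}, \code{"BR4"}.
#' @return character vector of lineage names.
#' @export
branch_taxa <- function(scaffold, br) {
  stopifnot(inherits(scaffold, "species_scaffold"))
  if (!br %in% names(scaffold$branches))
    stop("unknown hypothesis branch: ", br)
  scaffold$branches[[br]]
}

#' Serialize the scaffold topology to newick
#'
#' @param scaffold \code{species_scaffold}.
#' @return newick string.
#' @export
scaffold_newick <- function(scaffold) {
  stopifnot(inherits(scaffold, "species_scaffold"))
  ape::write.tree(scaffold$tree)
}

#' @export
print.species_scaffold <- function(x, ...) {
  cat("<species_scaffold> focal:", x$focal_species, "(", x$focal_lineage, ")\n")
  cat(" ", scaffold_newick(x), "\n")
  for (br in names(x$branches))
    cat(" ", br, "->", paste(x$branches[[br]], collapse = "+"), "\n")
  invisible(x)
}
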