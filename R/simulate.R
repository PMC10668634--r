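#' Planted gene program
#'
#' A block of genes carrying a group-dependent mean shift (log2 units)
#' on top of the baseline expression model. The planted analogue of a
#' biological expression program (e.g. an AT1, AT2 or embryonic
#' progenitor program).
#'
#' @slot name program name.
#' @slot geneIndices unique 1-based indices into the gene universe.
#' @slot effectLog2 named numeric: mean log2 shift per group label
#'   (must cover every group in the companion design).
#' @slot dispersion positive noise standard deviation (log2 units) for
#'   the program genes.
#' @export
setClass("GeneProgram",
  representation(name = "character", geneIndices = "integer",
                 effectLog2 = "numeric", dispersion = "numeric"))

setValidity("GeneProgram", function(object) {
  msg <- character()
  if (anyDuplicated(object@geneIndices))
    msg <- c(msg, "duplicate gene indices in program")
  if (any(object@geneIndices < 1L))
    msg <- c(msg, "gene indices must be >= 1")
  if (is.null(names(object@effectLog2)))
    msg <- c(msg, "effectLog2 must be named by group label")
  if (length(object@dispersion) != 1L || object@dispersion <= 0)
    msg <- c(msg, "dispersion must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneProgram-class
#' @param name,geneIndices,effectLog2,dispersion see slots.
#' @export
GeneProgram <- function(name, geneIndices, effectLog2, dispersion = 0.3) {
  new("GeneProgram", name = name, geneIndices = as.integer(geneIndices),
      effectLog2 = effectLog2, dispersion = dispersion)
}

#' Design of a simulated multi-group expression study
#'
#' @slot nGenes size of the gene universe.
#' @slot groups named integer: samples per group label (each >= 1).
#' @slot programs list of [GeneProgram-class]; overlapping programs are
#'   allowed (their effects add) and flagged with a message.
#' @slot noiseSd baseline noise sd (log2) for genes outside any program.
#' @slot seed integer seed.
#' @export
setClass("StudyDesign",
  representation(nGenes = "integer", groups = "integer",
                 programs = "list", noiseSd = "numeric", seed = "integer"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (is.null(names(object@groups)) || any(object@groups < 1L))
    msg <- c(msg, "groups must be a named vector of counts >= 1")
  for (p in object@programs) {
    if (!is(p, "GeneProgram")) {
      msg <- c(msg, "programs must be GeneProgram objects"); next
    }
    if (any(p@geneIndices > object@nGenes))
      msg <- c(msg, sprintf("program '%s' indexes beyond nGenes", p@name))
    missing <- setdiff(names(object@groups), names(p@effectLog2))
    if (length(missing))
      msg <- c(msg, sprintf("program '%s' lacks effects for group(s): %s",
                            p@name, paste(missing, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname StudyDesign-class
#' @param nGenes,groups,programs,noiseSd,seed see slots.
#' @export
StudyDesign <- function(nGenes, groups, programs = list(),
                        noiseSd = 0.3, seed = 7L) {
  new("StudyDesign", nGenes = as.integer(nGenes),
      groups = stats::setNames(as.integer(groups), names(groups)),
      programs = programs, noiseSd = noiseSd, seed = as.integer(seed))
}

geneUniverse <- function(n) sprintf("g%04d", seq_len(n))

#' Default three-population study design
#'
#' 2,000 genes; three groups of three samples each (typeI, typeII,
#' dualpos), mirroring a nine-sample sorted-population RNA-seq design.
#' Three non-overlapping 150-gene programs are planted: a typeI program
#' up (+2 log2) in typeI and dualpos, a typeII program up in typeII and
#' dualpos, and an embryonic-progenitor program up only in dualpos —
#' the dual-positive group thus literally shares both single-positive
#' programs and adds a progenitor program.
#'
#' @param seed integer seed.
#' @param effectLog2 planted effect size, default 2 (log2 units).
#' @param dispersion per-gene noise sd, default 0.3.
#' @return A [StudyDesign-class].
#' @export
defaultStudyDesign <- function(seed = 7L, effectLog2 = 2, dispersion = 0.3) {
  groups <- c(typeI = 3L, typeII = 3L, dualpos = 3L)
  eff <- function(...) {
    e <- c(...)
    out <- stats::setNames(numeric(length(groups)), names(groups))
    out[names(e)] <- e
    out
  }
  programs <- list(
    GeneProgram("typeI", 1:150,
                eff(typeI = effectLog2, dualpos = effectLog2), dispersion),
    GeneProgram("typeII", 151:300,
                eff(typeII = effectLog2, dualpos = effectLog2), dispersion),
    GeneProgram("embryonic", 301:450,
                eff(dualpos = effectLog2), dispersion))
  StudyDesign(2000L, groups, programs, noiseSd = dispersion, seed = seed)
}

#' Gene sets of the programs planted in a study design
#'
#' @param design a [StudyDesign-class].
#' @return A [GeneSetCollection-class], one set per planted program.
#' @export
programGeneSets <- function(design) {
  ids <- geneUniverse(design@nGenes)
  GeneSetCollection(lapply(design@programs, function(p)
    GeneSet(p@name, ids[p@geneIndices], "planted program")))
}

#' Simulate a multi-group expression study
#'
#' Log2-scale model: per-gene baseline mean ~ Normal(5, 1), plus the
#' planted program shift for the sample's group, plus Normal noise with
#' sd equal to the program's dispersion (baseline \code{noiseSd} for
#' genes outside every program). Deterministic given the design's seed.
#'
#' @param design a [StudyDesign-class].
#' @return list with elements \code{matrix} (log2-scale
#'   [ExpressionMatrix-class]) and \code{annotation} (data.frame with
#'   \code{sample_id}, \code{group}).
#' @export
simulateStudy <- function(design) {
  stopifnot(is(design, "StudyDesign"))
  validObject(design)
  allIdx <- unlist(lapply(design@programs, slot, "geneIndices"))
  if (anyDuplicated(allIdx))
    message("note: programs overlap on ",
            sum(duplicated(allIdx)), " gene(s); effects add")
  ids <- geneUniverse(design@nGenes)
  groupOf <- rep(names(design@groups), design@groups)
  sampleId <- paste0(groupOf, "_", unlist(lapply(design@groups, seq_len)))
  withSeed(design@seed, {
    baseline <- stats::rnorm(design@nGenes, mean = 5, sd = 1)
    shift <- matrix(0, design@nGenes, length(groupOf))
    sdGene <- rep(design@noiseSd, design@nGenes)
    for (p in design@programs) {
      sdGene[p@geneIndices] <- p@dispersion
      for (j in seq_along(groupOf))
        shift[p@geneIndices, j] <-
          shift[p@geneIndices, j] + p@effectLog2[[groupOf[j]]]
    }
    noise <- matrix(stats::rnorm(design@nGenes * length(groupOf), sd = sdGene),
                    design@nGenes, length(groupOf))
    vals <- baseline + shift + noise
  })
  dimnames(vals) <- list(ids, sampleId)
  list(matrix = ExpressionMatrix(vals, "log2"),
       annotation = data.frame(sample_id = sampleId, group = groupOf,
                               stringsAsFactors = FALSE))
}

#' Simulate reference expression panels for signature derivation
#'
#' Emulates the developmental reference datasets signatures are derived
#' from: three labeled panels on the same 2,000-gene universe as the
#' default study, each with two cell types of four samples and one
#' 150-gene program (+3 log2, sd 0.2) planted per cell type:
#' \itemize{
#'   \item \code{E11_5}: early \code{progenitor} (the study's embryonic
#'     program genes) vs \code{differentiated} (the typeII program).
#'   \item \code{E17_5}: late \code{progenitor} (a program half
#'     overlapping the embryonic one) vs \code{differentiated} (typeI
#'     program).
#'   \item \code{adult}: differentiated \code{AT1} (typeI program) vs
#'     \code{AT2} (typeII program).
#' }
#'
#' @param seed integer seed.
#' @return named list of panels, each a list with \code{matrix}
#'   (log2-scale [ExpressionMatrix-class]), \code{annotation}, and
#'   \code{planted} (named list of planted gene-index vectors).
#' @export
simulateReferencePanels <- function(seed = 1L) {
  plan <- list(
    E11_5 = list(progenitor = 301:450, differentiated = 151:300),
    E17_5 = list(progenitor = 376:525, differentiated = 1:150),
    adult = list(AT1 = 1:150, AT2 = 151:300))
  out <- vector("list", length(plan))
  names(out) <- names(plan)
  for (i in seq_along(plan)) {
    types <- names(plan[[i]])
    programs <- lapply(types, function(ty) {
      eff <- stats::setNames(rep(0, length(types)), types)
      eff[ty] <- 3
      GeneProgram(ty, plan[[i]][[ty]], eff, dispersion = 0.2)
    })
    design <- StudyDesign(2000L,
                          stats::setNames(rep(4L, length(types)), types),
                          programs, noiseSd = 0.2,
                          seed = childSeed(seed, 100 + i))
    sim <- simulateStudy(design)
    sim$annotation$sample_id <-
      paste0(names(plan)[i], "_", sim$annotation$sample_id)
    colnames(sim$matrix@values) <- sim$annotation$sample_id
    out[[i]] <- list(matrix = sim$matrix, annotation = sim$annotation,
                     planted = plan[[i]])
  }
  out
}

#' Simulate an oncogene-responsive cell-line reference panel
#'
#' Emulates a cell-line compendium restricted to an oncogene-responsive
#' gene module: the module rows have a planted nonnegative rank-k
#' structure (k latent transcriptional states; every cell line belongs
#' to one state) plus optional Gaussian noise, and 200 background genes
#' carry unstructured positive values. Gene ids come from the same
#' universe as the default study (module = genes 501..500+moduleSize),
#' so study samples can later be projected onto a map built from this
#' panel.
#'
#' @param nCellLines number of cell lines (>= 3 x \code{nStates}).
#' @param moduleSize size of the module gene set, default 1000.
#' @param nStates planted latent states, default 3.
#' @param noiseSd additive Gaussian noise sd (values re-clipped at 0),
#'   default 0.05.
#' @param seed integer seed.
#' @return list with \code{matrix} (raw-scale nonnegative
#'   [ExpressionMatrix-class]), \code{module} ([GeneSet-class]),
#'   \code{annotation} (cell line -> planted state label), and
#'   \code{Wtrue}/\code{Htrue} (the planted factors).
#' @export
simulateKrasPanel <- function(nCellLines = 60L, moduleSize = 1000L,
                              nStates = 3L, noiseSd = 0.05, seed = 11L) {
  stopIfNot(moduleSize >= 10L, "moduleSize must be >= 10")
  stopIfNot(nCellLines >= 3L * nStates,
            "need at least 3 cell lines per planted state")
  nBackground <- 200L
  nUniverse <- 2000L
  stopIfNot(moduleSize + 500L + nBackground <= nUniverse,
            "moduleSize too large for the gene universe")
  ids <- geneUniverse(nUniverse)
  moduleIds <- ids[500L + seq_len(moduleSize)]
  bgIds <- ids[500L + moduleSize + seq_len(nBackground)]
  lines <- sprintf("cellline_%02d", seq_len(nCellLines))
  state <- rep_len(seq_len(nStates), nCellLines)
  withSeed(seed, {
    Wtrue <- matrix(stats::rexp(moduleSize * nStates, rate = 1),
                    moduleSize, nStates)
    Htrue <- matrix(0.02 * stats::runif(nStates * nCellLines),
                    nStates, nCellLines)
    Htrue[cbind(state, seq_len(nCellLines))] <- 1
    vals <- Wtrue %*% Htrue * 5
    if (noiseSd > 0)
      vals <- pmax(vals + stats::rnorm(length(vals), sd = noiseSd), 0)
    bg <- matrix(stats::runif(nBackground * nCellLines, 0.5, 1.5),
                 nBackground, nCellLines)
  })
  full <- rbind(vals, bg)
  dimnames(full) <- list(c(moduleIds, bgIds), lines)
  list(matrix = ExpressionMatrix(full, "raw"),
       module = GeneSet("KRAS_module", moduleIds,
                        "planted oncogene-responsive module"),
       annotation = data.frame(sample_id = lines,
                               group = paste0("state", state),
                               stringsAsFactors = FALSE),
       Wtrue = Wtrue, Htrue = Htrue)
}

#' Plant cell-line state activity into study samples
#'
#' Adds, to the selected samples of a log2-scale study matrix, a scaled
#' standardized copy of the mean module-gene profile of one planted
#' state of a cell-line panel. Used to make a sample group carry a
#' specific oncogenic-state program so that map projection can recover
#' it.
#'
#' @param m log2-scale [ExpressionMatrix-class].
#' @param sampleIds samples to modify.
#' @param panel result of [simulateKrasPanel()].
#' @param state planted state index to copy.
#' @param scale log2-units amplitude of the added pattern, default 2.
#' @return the modified [ExpressionMatrix-class].
#' @export
addStateActivity <- function(m, sampleIds, panel, state, scale = 2) {
  stopifnot(is(m, "ExpressionMatrix"))
  moduleIds <- intersect(panel$module@genes, geneIds(m))
  stopIfNot(length(moduleIds) > 0, "no module genes present in matrix")
  inState <- panel$annotation$group == paste0("state", state)
  stopIfNot(any(inState), "no cell line in state ", state)
  prof <- rowMeans(exprValues(panel$matrix)[moduleIds, inState,
                                            drop = FALSE])
  pattern <- (prof - mean(prof)) / stats::sd(prof)
  v <- m@values
  v[moduleIds, sampleIds] <- v[moduleIds, sampleIds] + scale * pattern
  ExpressionMatrix(v, m@scaleTag)
}

#' Specification of a simulated cell population with marker intensities
#'
#' @slot nCells number of cells to draw.
#' @slot fractions named label -> proportion map, summing to 1.
#' @slot markerMeans named list: label -> named numeric of mean log10
#'   marker intensities; the marker set must be identical across labels.
#' @slot markerSd common intensity sd (log10), default 0.5.
#' @slot seed integer seed.
#' @export
setClass("CellPopulationSpec",
  representation(nCells = "integer", fractions = "numeric",
                 markerMeans = "list", markerSd = "numeric",
                 seed = "integer"))

setValidity("CellPopulationSpec", function(object) {
  msg <- character()
  if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
  f <- object@fractions
  if (is.null(names(f))) msg <- c(msg, "fractions must be named")
  if (any(f < 0) || any(f > 1)) msg <- c(msg, "fractions must lie in [0,1]")
  if (abs(sum(f) - 1) > 1e-9) msg <- c(msg, "fractions must sum to 1")
  if (!setequal(names(f), names(object@markerMeans)))
    msg <- c(msg, "markerMeans must cover exactly the fraction labels")
  mk <- lapply(object@markerMeans, names)
  if (length(mk) > 1 && !all(vapply(mk[-1], identical, logical(1), mk[[1]])))
    msg <- c(msg, "marker set must be identical across labels")
  if (length(object@markerSd) != 1L || object@markerSd <= 0)
    msg <- c(msg, "markerSd must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname CellPopulationSpec-class
#' @param nCells,fractions,markerMeans,markerSd,seed see slots.
#' @export
CellPopulationSpec <- function(nCells, fractions, markerMeans,
                               markerSd = 0.5, seed = 7L) {
  new("CellPopulationSpec", nCells = as.integer(nCells),
      fractions = fractions, markerMeans = markerMeans,
      markerSd = markerSd, seed = as.integer(seed))
}

#' Default epithelial population spec (two-marker sorting experiment)
#'
#' Three populations on PDPN / TdTm markers, with the dual-positive
#' population high on both markers. Negative marker level 0.5 and
#' positive level 4.5 (log10 units, sd 0.5) keep populations well
#' separated so that midpoint gates misclassify a negligible fraction.
#' The default dual-positive abundance is the 2.6\% reported for
#' oncogene-activated mouse lung epithelium; the remainder is split
#' with AT2 cells roughly twice as abundant as AT1, as in alveolar
#' epithelium.
#'
#' @param nCells number of cells, default 100000.
#' @param fractions named proportions for typeI/typeII/dualpos.
#' @param seed integer seed.
#' @return A [CellPopulationSpec-class].
#' @export
epithelialPopulationSpec <- function(nCells = 100000L,
                                     fractions = c(typeI = 0.324,
                                                   typeII = 0.650,
                                                   dualpos = 0.026),
                                     seed = 7L) {
  lo <- 0.5; hi <- 4.5
  means <- list(typeI = c(PDPN = hi, TdTm = lo),
                typeII = c(PDPN = lo, TdTm = hi),
                dualpos = c(PDPN = hi, TdTm = hi))
  CellPopulationSpec(nCells, fractions, means[names(fractions)],
                     markerSd = 0.5, seed = seed)
}

#' Simulate a table of single cells with marker intensities
#'
#' Each cell's label is drawn from the population fractions and each
#' marker intensity from that label's Normal model (independent markers,
#' common sd). Deterministic given the spec's seed.
#'
#' @param spec a [CellPopulationSpec-class].
#' @return data.frame with \code{cell_id}, one column per marker, and
#'   \code{true_label}.
#' @export
simulateCells <- function(spec) {
  stopifnot(is(spec, "CellPopulationSpec"))
  validObject(spec)
  labels <- names(spec@fractions)
  markers <- names(spec@markerMeans[[1]])
  withSeed(spec@seed, {
    lab <- sample(labels, spec@nCells, replace = TRUE,
                  prob = spec@fractions)
    vals <- sapply(markers, function(mk) {
      mu <- vapply(spec@markerMeans, `[[`, numeric(1), mk)[lab]
      stats::rnorm(spec@nCells, mean = mu, sd = spec@markerSd)
    })
  })
  if (spec@nCells == 1L) vals <- matrix(vals, nrow = 1,
                                        dimnames = list(NULL, markers))
  out <- data.frame(cell_id = sprintf("cell_%06d", seq_len(spec@nCells)),
                    vals, true_label = lab, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a qPCR CT table with known fold changes
#'
#' CT values are constructed by inverting the delta-delta-CT formula:
#' with zero noise, [foldChange()] on the output recovers
#' \code{trueFoldChanges} exactly. The housekeeping gene is fixed at
#' CT 18 and the control-condition target at CT 24; the treated target
#' CT is 24 - log2(fold change). Optional Gaussian noise (sd
#' \code{noiseSd}) is added to every individual CT measurement.
#'
#' @param trueFoldChanges named positive numeric: gene -> fold change.
#' @param noiseSd CT measurement noise sd, default 0.
#' @param nReplicates replicates per condition, default 3.
#' @param housekeepingGene housekeeping gene id, default "GAPDH".
#' @param seed integer seed.
#' @return data.frame with \code{sample_id}, \code{condition},
#'   \code{gene_id}, \code{ct}.
#' @export
simulateCtTable <- function(trueFoldChanges, noiseSd = 0,
                            nReplicates = 3L, housekeepingGene = "GAPDH",
                            seed = 7L) {
  stopIfNot(length(trueFoldChanges) >= 1L &&
              !is.null(names(trueFoldChanges)),
            "trueFoldChanges must be a named vector")
  stopIfNot(all(trueFoldChanges > 0), "fold changes must be positive")
  genes <- names(trueFoldChanges)
  rows <- expand.grid(replicate = seq_len(nReplicates),
                      condition = c("control", "treated"),
                      gene_id = c(genes, housekeepingGene),
                      stringsAsFactors = FALSE)
  ct <- ifelse(rows$gene_id == housekeepingGene, 18,
               ifelse(rows$condition == "control", 24,
                      24 - log2(trueFoldChanges[rows$gene_id])))
  if (noiseSd > 0)
    ct <- ct + withSeed(seed, stats::rnorm(length(ct), sd = noiseSd))
  data.frame(sample_id = paste0(rows$condition, "_", rows$replicate),
             condition = rows$condition, gene_id = rows$gene_id,
             ct = as.numeric(ct), stringsAsFactors = FALSE)
}
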