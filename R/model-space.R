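## Model spaces: the 24 network architectures over the eight-source
## somatosensory hierarchy (Step 1) and the factorial space of contextual
## modulation models (Step 2).

.allSources <- c("lS1", "rS1", "lS2", "rS2", "lIFG", "rIFG", "lIPC", "rIPC")
.regions <- c("S1", "S2", "IFG", "IPC")

# reciprocal intra-hemispheric link: forward lower -> upper, matching
# backward, in both hemispheres
.recipEdges <- function(lower, upper) {
  do.call(rbind, lapply(c("l", "r"), function(h)
    data.frame(from = paste0(h, c(lower, upper)),
               to = paste0(h, c(upper, lower)),
               type = c("forward", "backward"),
               stringsAsFactors = FALSE)))
}

# homotopic interhemispheric link (reciprocal forward + backward both ways)
.homotopicEdges <- function(region) {
  l <- paste0("l", region); r <- paste0("r", region)
  data.frame(from = c(l, r, l, r), to = c(r, l, r, l),
             type = c("forward", "forward", "backward", "backward"),
             stringsAsFactors = FALSE)
}

.architecture <- function(id, edges, hierarchyOrder) {
  structure(list(id = id, sources = .allSources, edges = edges,
                 hierarchyOrder = hierarchyOrder,
                 label = paste0("M", id)),
            class = "cmcArchitecture")
}

#' @export
print.cmcArchitecture <- function(x, ...) {
  cat(x$label, ": ", nrow(x$edges), " directed extrinsic connections, ",
      "hierarchy ", x$hierarchyOrder, "\n", sep = "")
  invisible(x)
}

#' Pre-partition baseline network
#'
#' The simplest generable network: bilateral S1 and S2 with reciprocal
#' intra-hemispheric connections only (no fronto-parietal nodes connected).
#'
#' @return a \code{cmcArchitecture}.
#' @export
baselineArchitecture <- function() {
  .architecture(0, .recipEdges("S1", "S2"), "single_high_node")
}

#' Enumerate the Step-1 architecture space
#'
#' Builds the 24 candidate network architectures over the eight sources
#' (bilateral S1, S2, IFG, IPC). All architectures include reciprocal
#' bilateral S1-S2 connections; they differ in which fronto-parietal nodes
#' are connected and how. Models 1-3 connect the somatosensory regions to
#' IFG only (S1-IFG / S2-IFG / both), models 13-15 to IPC only; models 4-12
#' (IPC hierarchically above IFG) and 16-24 (IFG above IPC) connect both
#' nodes, crossing S1 connectivity \{IFG, IPC, both\} with S2 connectivity
#' \{IFG, IPC, both\}. Whenever a fronto-parietal node is connected,
#' homotopic interhemispheric connections between its two hemispheres are
#' included; all connections are reciprocal (forward + matching backward).
#'
#' @return list of 24 \code{cmcArchitecture} objects (ids 1-24).
#' @export
enumerateArchitectures <- function() {
  base <- .recipEdges("S1", "S2")
  singleNode <- function(idStart, node) {
    lapply(0:2, function(k) {
      edges <- base
      if (k %in% c(0, 2)) edges <- rbind(edges, .recipEdges("S1", node))
      if (k %in% c(1, 2)) edges <- rbind(edges, .recipEdges("S2", node))
      edges <- rbind(edges, .homotopicEdges(node))
      .architecture(idStart + k, edges, "single_high_node")
    })
  }
  bothNode <- function(idStart, order) {
    lowHigh <- if (order == "IPC_above_IFG") c("IFG", "IPC")
               else c("IPC", "IFG")
    out <- list()
    opts <- list("IFG", "IPC", c("IFG", "IPC"))
    k <- 0
    for (s1 in opts) for (s2 in opts) {
      edges <- base
      for (tgt in s1) edges <- rbind(edges, .recipEdges("S1", tgt))
      for (tgt in s2) edges <- rbind(edges, .recipEdges("S2", tgt))
      edges <- rbind(edges, .recipEdges(lowHigh[1], lowHigh[2]),
                     .homotopicEdges("IFG"), .homotopicEdges("IPC"))
      k <- k + 1
      out[[k]] <- .architecture(idStart + k - 1, edges, order)
    }
    out
  }
  c(singleNode(1, "IFG"), bothNode(4, "IPC_above_IFG"),
    singleNode(13, "IPC"), bothNode(16, "IFG_above_IPC"))
}

#' Extrinsic connection masks of an architecture
#'
#' @param arch a \code{cmcArchitecture}.
#' @return list with 0/1 matrices \code{AF} and \code{AB} (target x origin)
#'   over the architecture's sources.
#' @export
architectureMasks <- function(arch) {
  n <- length(arch$sources)
  AF <- AB <- matrix(0, n, n, dimnames = list(arch$sources, arch$sources))
  for (i in seq_len(nrow(arch$edges))) {
    e <- arch$edges[i, ]
    if (e$type == "forward") AF[e$to, e$from] <- 1 else AB[e$to, e$from] <- 1
  }
  list(AF = AF, AB = AB)
}

## ---- Step-2 modulation models -------------------------------------------

.modModel <- function(id, kind, family, scope, extrinsic, label = NULL) {
  structure(list(id = id, kind = kind, family = family, scope = scope,
                 extrinsic = extrinsic,
                 label = if (is.null(label)) paste0("M", id) else label),
            class = "cmcModulationModel")
}

#' @export
print.cmcModulationModel <- function(x, ...) {
  on <- names(x$scope)[x$scope != "none"]
  cat(x$label, " (", x$kind, ", ", x$family, "): ",
      if (length(on)) paste(paste0(on, "[", x$scope[on], "]"),
                            collapse = " ") else "null",
      if (x$extrinsic) " + recurrent extrinsic" else "", "\n", sep = "")
  invisible(x)
}

.nullScope <- function() setNames(rep("none", 4), .regions)

# The 12 bilateral gain-site combinations ship as an explicit JSON list
# (inst/extdata/bilateral_models.json); the selection and ordering are a
# package reading of the factorial figure and are fully overridable.
.loadBilateral <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "bilateral_models.json",
                        package = "painDCM")
  lst <- jsonlite::read_json(file, simplifyVector = FALSE)
  lapply(lst, function(x) unlist(x, use.names = FALSE))
}

#' Enumerate the attention modulation models
#'
#' Thirteen models of top-down attentional modulation of intrinsic
#' (superficial-pyramidal gain) connectivity: one null model (id 0) plus the
#' twelve shipped bilateral gain-site combinations over \{S1, S2, IFG,
#' IPC\} (ids 1-12). Attention never modulates extrinsic connectivity.
#'
#' @param bilateralFile optional path to an alternative JSON list of
#'   bilateral gain-site combinations.
#' @return list of \code{cmcModulationModel} objects.
#' @export
enumerateAttentionModels <- function(bilateralFile = NULL) {
  combos <- .loadBilateral(bilateralFile)
  if (!all(vapply(combos, function(x) all(x %in% .regions), TRUE)))
    stop("configuration error: malformed bilateral model list",
         call. = FALSE)
  out <- list(.modModel(0, "attention", "null", .nullScope(), FALSE,
                        "M0-null"))
  for (i in seq_along(combos)) {
    sc <- .nullScope()
    sc[combos[[i]]] <- "bilateral"
    out[[i + 1]] <- .modModel(i, "attention", "bilateral", sc, FALSE)
  }
  out
}

#' Enumerate the expectation-violation modulation models
#'
#' Twenty-nine models of modulation by expectation violation: one null
#' model (id 0), the twelve bilateral gain-site combinations (ids 1-12),
#' and sixteen contralateral-family models (ids 13-28) built as four
#' somatosensory families — contralateral S1; contralateral S2;
#' contralateral S1 and S2; contralateral S1 with bilateral S2 — each
#' crossed with bilateral IFG and/or IPC gain (none / IFG / IPC / both).
#' All non-null models additionally allow modulation of recurrent
#' (feedforward and feedback) extrinsic connectivity.
#'
#' @inheritParams enumerateAttentionModels
#' @return list of \code{cmcModulationModel} objects.
#' @export
enumerateEVModels <- function(bilateralFile = NULL) {
  combos <- .loadBilateral(bilateralFile)
  out <- list(.modModel(0, "ev", "null", .nullScope(), FALSE, "M0-null"))
  for (i in seq_along(combos)) {
    sc <- .nullScope()
    sc[combos[[i]]] <- "bilateral"
    out[[i + 1]] <- .modModel(i, "ev", "bilateral", sc, TRUE,
                              paste0("B", i))
  }
  fams <- list(c(S1 = "contralateral"),
               c(S2 = "contralateral"),
               c(S1 = "contralateral", S2 = "contralateral"),
               c(S1 = "contralateral", S2 = "bilateral"))
  fp <- list(character(0), "IFG", "IPC", c("IFG", "IPC"))
  id <- 12
  for (f in fams) for (g in fp) {
    sc <- .nullScope()
    sc[names(f)] <- f
    sc[g] <- "bilateral"
    id <- id + 1
    out[[id + 1]] <- .modModel(id, "ev", "contralateral", sc, TRUE,
                               paste0("C", id - 12))
  }
  out
}

#' Cross the attention and expectation-violation factors
#'
#' Full Cartesian product of the two modulation factors with stable
#' composite ids.
#'
#' @param attentionModels,evModels model lists from
#'   [enumerateAttentionModels()] / [enumerateEVModels()].
#' @return object of class \code{cmcModelSpace}: the two component lists
#'   plus a \code{crossed} data.frame (attentionId, evId, compositeId).
#' @export
crossFactorial <- function(attentionModels = enumerateAttentionModels(),
                           evModels = enumerateEVModels()) {
  stopifnot(length(attentionModels) > 0, length(evModels) > 0)
  aId <- vapply(attentionModels, `[[`, 0, "id")
  eId <- vapply(evModels, `[[`, 0, "id")
  crossed <- expand.grid(attentionId = aId, evId = eId,
                         KEEP.OUT.ATTRS = FALSE)
  crossed$compositeId <- paste0("A", crossed$attentionId,
                                "xE", crossed$evId)
  structure(list(attentionModels = attentionModels, evModels = evModels,
                 crossed = crossed),
            class = "cmcModelSpace")
}

#' @export
print.cmcModelSpace <- function(x, ...) {
  cat("cmcModelSpace:", length(x$attentionModels), "attention x",
      length(x$evModels), "expectation-violation models =",
      nrow(x$crossed), "crossed models\n")
  invisible(x)
}

#' Serialize a model space to JSON
#'
#' One object per model: id, kind, family, gain-site scopes, extrinsic
#' flag; architectures serialize their edge lists.
#'
#' @param x a \code{cmcModelSpace}, a list of architectures, or a list of
#'   modulation models.
#' @param file output path.
#' @export
writeModelSpace <- function(x, file) {
  ser <- function(m) {
    if (inherits(m, "cmcArchitecture"))
      list(id = m$id, hierarchy = m$hierarchyOrder,
           edges = m$edges)
    else list(id = m$id, kind = m$kind, family = m$family,
              scope = as.list(m$scope), extrinsic = m$extrinsic)
  }
  obj <- if (inherits(x, "cmcModelSpace"))
    list(attention = lapply(x$attentionModels, ser),
         ev = lapply(x$evModels, ser), crossed = x$crossed)
  else lapply(x, ser)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
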