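## Roving-oddball stimulus design: blocks of stimulus trains delivered to
## alternating hands at a fixed 1 s inter-stimulus interval. The first
## stimulus of each train (the location change) is the deviant; only the
## last repetition before the next change is modelled as a standard, so that
## deviant and standard trial counts are balanced.

.defaultRepProbs <- c(0.05, 0.15, 0.60, 0.15, 0.05) # train lengths 3..7

#' Derive a per-block seed from a session master seed
#'
#' Counter scheme: \code{(master + 104729 * block) mod (2^31 - 1)}, so each
#' block is independently reproducible from the master seed and its index.
#'
#' @param masterSeed session master seed.
#' @param blockIndex 1-based block index.
#' @export
blockSeed <- function(masterSeed, blockIndex) {
  as.integer((as.numeric(masterSeed) + 104729 * blockIndex) %% 2147483647)
}

#' Generate one roving-oddball block
#'
#' Draws \code{nTrains} i.i.d. train lengths from \code{repProbs} (lengths 3
#' to 7), alternates the stimulated hand between consecutive trains, spaces
#' events 1000 ms apart, and labels each event: the train-initial stimulus
#' is a deviant, the final repetition of a train followed by another train
#' is a standard, all other repetitions are fillers.
#'
#' In the alternative \code{mode = "fixed-budget"} the block instead draws
#' trains until a fixed stimulus budget is reached (truncating the final
#' train), giving a variable number of trains/deviants per block.
#'
#' @param attention "attended" or "unattended".
#' @param nTrains number of trains (>= 1); under \code{"fixed-budget"} the
#'   budget is \code{nTrains * 5} stimuli.
#' @param repProbs probability vector over train lengths 3-7 (5 entries
#'   summing to 1 within 1e-9).
#' @param firstHand hand of the first train ("left"/"right").
#' @param seed integer seed; identical seeds give identical blocks.
#' @param mode "fixed-trains" (default) or "fixed-budget".
#' @return a data.frame of events with columns time_ms, hand, role,
#'   train_index, position_in_train, and attributes \code{attention} and
#'   \code{nTrains}.
#' @export
generateBlock <- function(attention = c("unattended", "attended"),
                          nTrains = 25, repProbs = .defaultRepProbs,
                          firstHand = c("left", "right"), seed = 1L,
                          mode = c("fixed-trains", "fixed-budget")) {
  attention <- match.arg(attention)
  firstHand <- match.arg(firstHand)
  mode <- match.arg(mode)
  if (length(repProbs) != 5 || any(repProbs < 0) ||
      abs(sum(repProbs) - 1) > 1e-9)
    stop("configuration error: repProbs must be 5 nonnegative entries ",
         "summing to 1", call. = FALSE)
  if (nTrains < 1) stop("nTrains must be >= 1", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (mode == "fixed-trains") {
    lens <- sample(3:7, nTrains, replace = TRUE, prob = repProbs)
  } else {
    budget <- nTrains * 5
    lens <- integer(0)
    while (sum(lens) < budget)
      lens <- c(lens, sample(3:7, 1, prob = repProbs))
    excess <- sum(lens) - budget
    lens[length(lens)] <- lens[length(lens)] - excess
    lens <- lens[lens > 0]
  }
  n <- length(lens)
  hands <- rep(c(firstHand, setdiff(c("left", "right"), firstHand)),
               length.out = n)
  ev <- data.frame(
    time_ms = 1000 * (seq_len(sum(lens)) - 1),
    hand = rep(hands, lens),
    role = "filler",
    train_index = rep(seq_len(n) - 1L, lens),
    position_in_train = unlist(lapply(lens, function(l) seq_len(l) - 1L)),
    stringsAsFactors = FALSE)
  ev$role[ev$position_in_train == 0] <- "deviant"
  lastPos <- rep(lens - 1L, lens)
  followed <- rep(seq_len(n) < n, lens)
  ev$role[ev$position_in_train == lastPos & followed] <- "standard"
  # fixation-cross colour changes every 2-5 s: metadata only
  ct <- cumsum(runif(ceiling(sum(lens) / 2), 2000, 5000))
  ct <- ct[ct < max(ev$time_ms)]
  attr(ev, "attention") <- attention
  attr(ev, "nTrains") <- n
  attr(ev, "crossTimes") <- ct
  ev
}

#' Generate a full roving-oddball session
#'
#' Assembles \code{nBlocks} blocks with attention labels given by
#' \code{order} (A = unattended, B = attended; the two counterbalanced
#' orders are ABBABAAB and BAABABBA) and per-block seeds derived from the
#' master seed via [blockSeed()]. The first hand alternates across blocks
#' to balance laterality. Under the default fixed-trains mode the session
#' contains exactly \code{nBlocks * nTrainsPerBlock} deviants.
#'
#' @param nBlocks number of blocks (default 8).
#' @param nTrainsPerBlock trains per block (default 25).
#' @param repProbs train-length distribution (lengths 3-7).
#' @param order "ABBABAAB", "BAABABBA", or any string over \{A, B\} of
#'   length \code{nBlocks}.
#' @param seed session master seed.
#' @param mode see [generateBlock()].
#' @return a [SessionDesign-class] object.
#' @export
generateSession <- function(nBlocks = 8, nTrainsPerBlock = 25,
                            repProbs = .defaultRepProbs,
                            order = "ABBABAAB", seed = 1L,
                            mode = "fixed-trains") {
  labs <- strsplit(order, "")[[1]]
  if (nBlocks > 0 && length(labs) != nBlocks)
    stop("configuration error: order length must equal nBlocks",
         call. = FALSE)
  if (!all(labs %in% c("A", "B")))
    stop("configuration error: order must be a string over {A, B}",
         call. = FALSE)
  events <- list(); crosses <- list()
  for (b in seq_len(nBlocks)) {
    att <- if (labs[b] == "B") "attended" else "unattended"
    fh <- if (b %% 2 == 1) "left" else "right"
    blk <- generateBlock(att, nTrainsPerBlock, repProbs, fh,
                         seed = blockSeed(seed, b), mode = mode)
    blk$block <- b
    blk$attention <- att
    crosses[[b]] <- data.frame(block = b,
                               time_ms = attr(blk, "crossTimes"))
    events[[b]] <- blk
  }
  ev <- if (nBlocks > 0) do.call(rbind, events) else
    data.frame(time_ms = numeric(0), hand = character(0),
               role = character(0), train_index = integer(0),
               position_in_train = integer(0), block = integer(0),
               attention = character(0))
  ev <- ev[, c("block", "attention", "time_ms", "hand", "role",
               "train_index", "position_in_train")]
  rownames(ev) <- NULL
  cr <- if (nBlocks > 0) do.call(rbind, crosses) else
    data.frame(block = integer(0), time_ms = numeric(0))
  new("SessionDesign", events = ev, blockOrder = order,
      repProbs = repProbs, crossEvents = cr)
}

#' @describeIn generateSession the event table of a session.
#' @param design a [SessionDesign-class] object.
#' @export
designEvents <- function(design) design@events

setMethod("show", "SessionDesign", function(object) {
  ev <- object@events
  cat("SessionDesign:", length(unique(ev$block)), "blocks,", nrow(ev),
      "stimuli (", sum(ev$role == "deviant"), "deviants,",
      sum(ev$role == "standard"), "standards ), order",
      object@blockOrder, "\n")
})

#' Condition counts of a session
#'
#' Counts deviant and standard events in each of the eight cells of the
#' attention (u/a) x laterality (L/R) x expectation (D/S) design; fillers
#' are excluded, matching the balanced-design rule of one standard per
#' train.
#'
#' @param design a [SessionDesign-class] object.
#' @return named integer vector over the cells uLS, uLD, uRS, uRD, aLS,
#'   aLD, aRS, aRD.
#' @export
conditionTable <- function(design) {
  ev <- design@events
  if (nrow(ev) == 0) stop("design is empty", call. = FALSE)
  ev <- ev[ev$role %in% c("deviant", "standard"), ]
  lab <- paste0(ifelse(ev$attention == "attended", "a", "u"),
                ifelse(ev$hand == "left", "L", "R"),
                ifelse(ev$role == "deviant", "D", "S"))
  cells <- c("uLS", "uLD", "uRS", "uRD", "aLS", "aLD", "aRS", "aRD")
  out <- setNames(integer(8), cells)
  tab <- table(lab)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Write a session design to CSV (events) and JSON (condition counts)
#'
#' @param design a [SessionDesign-class] object.
#' @param csvFile path for the event table.
#' @param jsonFile optional path for the JSON condition-count summary.
#' @export
writeDesign <- function(design, csvFile, jsonFile = NULL) {
  write.csv(design@events, csvFile, row.names = FALSE)
  if (!is.null(jsonFile))
    jsonlite::write_json(as.list(conditionTable(design)), jsonFile,
                         auto_unbox = TRUE)
  invisible(csvFile)
}
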