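#' Worked-example transcripts
#'
#' Deterministic synthetic transcripts realizing the canonical translation
#' scenarios the package models. Sequences are assembled from fixed codon
#' blocks (the neutral filler `GGA` repeat is stop-free and AUG-free in every
#' reading frame), so all structural counts are exact.
#'
#' * `make_fig3_transcript()` -- an mRNA with three start codons in two
#'   reading frames: an upstream AUG opening the short, reinitiation-eligible
#'   translon T1; a CUG within T1's span, in frame with the downstream main
#'   AUG, opening translon T3 (an N-terminally extended proteoform of T2's
#'   product); and the main AUG opening translon T2. Alternative initiation
#'   and reinitiation give exactly five ribosome paths. `probs` holds the
#'   canonical branch-probability assignment used by the simulation and
#'   recovery examples: 0.5 (upstream AUG), 0.3 (CUG), 0.9 (reinitiation),
#'   with the main AUG treated as a deterministic (probability 1) start.
#' * `make_delayed_reinit_transcript()` -- short uORF, long uORF overlapping
#'   the CDS start, and the CDS: the minimal layout for delayed reinitiation.
#'   The STEP recharge presets mirror normal versus stress conditions: under
#'   `"normal"` the post-termination ribosome regains competence before the
#'   long uORF start and reinitiates there; under `"stress"` the recharge
#'   distance carries it past the long uORF to the CDS start.
#' * `make_readthrough_transcript()` -- one AUG translon with a
#'   selenocysteine (UGA readthrough) event at its first stop, giving two
#'   product variants sharing a start.
#' * `make_frameshift_transcript()` -- one AUG translon with a -1 programmed
#'   frameshift site, giving a two-segment trans-frame translon alongside the
#'   in-frame product.
#' * `make_variant_fixture()` -- a 5' leader with a leaky upstream AUG and a
#'   strong (deterministic) in-frame AUG whose short translons feed the CDS
#'   by reinitiation, plus a single-nucleotide insertion that shifts the
#'   leader frame, extends both leader translons past the CDS start,
#'   introduces a new AUG, and leaves the CDS start unreachable.
#'
#' @param condition recharge preset for the delayed-reinitiation fixture.
#' @return A list with elements `transcript`, `events`, `policy` and, where
#'   applicable, `probs` (canonical branch probabilities), `variant` (a
#'   [variant_spec()]) and `cds_translon` (id of the CDS translon).
#' @examples
#' fx <- make_fig3_transcript()
#' count_paths(build_rdg(fx$transcript, fx$events, fx$policy))
#' @name fixtures
NULL

gga_fill <- function(n_codons) strrep("GGA", n_codons)

#' @rdname fixtures
#' @export
make_fig3_transcript <- function() {
  seq <- paste0(
    "GGCGGC",             # 5' leader [0,6)
    "AUG", "GCU", "GGA", "UAA",  # T1: [6,18), stop at 15; CUG at 10 in frame 1
    "CCAC",               # spacer [18,22), keeps frame 1 stop-free
    "AUG",                # main start at 22 (frame 1)
    gga_fill(33),         # CDS body [25,124)
    "UAA",                # shared stop at 124 (frame 1)
    "GGCGGC"              # 3' trailer
  )
  tx <- transcript("fig3_like", seq)
  stopifnot(codon_at(tx, 6) == "AUG", codon_at(tx, 10) == "CUG",
            codon_at(tx, 22) == "AUG",
            next_in_frame_stop(tx, 9, 0L) == 15,
            next_in_frame_stop(tx, 13, 1L) == 124)
  events <- list(
    initiation_event(6, "AUG", name = "T1"),
    initiation_event(10, "CUG", name = "T3"),
    initiation_event(22, "AUG", name = "T2")
  )
  list(
    transcript = tx,
    events = events,
    policy = reinitiation_policy(max_translon_nt = 100),
    probs = c("init@6" = 0.5, "init@10" = 0.3, "init@22" = 1.0,
              "reinit@15:T1" = 0.9)
  )
}

#' @rdname fixtures
#' @export
make_delayed_reinit_transcript <- function(condition = c("normal",
                                                         "stress")) {
  condition <- match.arg(condition)
  seq <- paste0(
    "GGCGGC",                  # [0,6)
    "AUG", "GGA", "GGA", "UAA",  # short uORF [6,18), stop at 15
    gga_fill(4),               # spacer [18,30)
    "AUG",                     # long uORF start at 30 (frame 0)
    gga_fill(14),              # [33,75)
    "GAU", "GGA",              # places CDS AUG at 76 (frame 1)
    gga_fill(38),              # [81,195)
    "GUA", "AGG",              # places CDS stop UAA at 196 (frame 1)
    gga_fill(6),               # [201,219)
    "UAA",                     # long uORF stop at 219 (frame 0)
    "GGAGGA"
  )
  tx <- transcript("delayed_reinit_mock", seq)
  stopifnot(codon_at(tx, 6) == "AUG", codon_at(tx, 30) == "AUG",
            codon_at(tx, 76) == "AUG",
            next_in_frame_stop(tx, 9, 0L) == 15,
            next_in_frame_stop(tx, 33, 0L) == 219,
            next_in_frame_stop(tx, 79, 1L) == 196)
  events <- list(
    initiation_event(6, "AUG"),
    initiation_event(30, "AUG"),
    initiation_event(76, "AUG")
  )
  recharge <- if (condition == "normal") 10L else 60L
  list(
    transcript = tx,
    events = events,
    policy = reinitiation_policy(max_translon_nt = 100,
                                 recharge_model = "STEP",
                                 recharge_distance_nt = recharge),
    condition = condition
  )
}

#' @rdname fixtures
#' @export
make_readthrough_transcript <- function() {
  seq <- paste0(
    "GGCGGC",
    "AUG", gga_fill(9),   # [6,36)
    "UGA",                # recoded stop at 36
    gga_fill(9),          # [39,66)
    "UAA",                # terminal stop at 66
    "GGAGGA"
  )
  tx <- transcript("selenoprotein_like", seq)
  stopifnot(codon_at(tx, 6) == "AUG",
            next_in_frame_stop(tx, 9, 0L) == 36,
            next_in_frame_stop(tx, 39, 0L) == 66)
  list(
    transcript = tx,
    events = list(initiation_event(6, "AUG"), selenocysteine_event(36)),
    policy = reinitiation_policy(max_translon_nt = 100)
  )
}

#' @rdname fixtures
#' @export
make_frameshift_transcript <- function() {
  seq <- paste0(
    "GGCGGC",
    "AUG", gga_fill(4),   # [6,21)
    gga_fill(7),          # slippery region and beyond [21,42)
    "UAG",                # in-frame (frame 0) stop at 42
    "GGA", "GGU", "AAG",  # places UAA at 50 (frame 2, the shifted frame)
    gga_fill(3)
  )
  tx <- transcript("frameshift_like", seq)
  stopifnot(codon_at(tx, 6) == "AUG",
            next_in_frame_stop(tx, 9, 0L) == 42,
            next_in_frame_stop(tx, 20, 2L) == 50)
  list(
    transcript = tx,
    events = list(initiation_event(6, "AUG"), frameshift_event(21, -1L)),
    policy = reinitiation_policy(max_translon_nt = 100)
  )
}

#' @rdname fixtures
#' @export
make_variant_fixture <- function() {
  seq <- paste0(
    "GGCGGC",
    "AUG", gga_fill(3),   # leaky upstream AUG at 6; [9,18)
    "AUG", gga_fill(8),   # strong in-frame AUG at 18; [21,45)
    "UAA",                # shared leader stop at 45
    gga_fill(4),          # [48,60)
    "AUG",                # CDS start at 60 (frame 0)
    gga_fill(35),         # [63,168)
    "UAA",                # CDS stop at 168
    "GGU", "AAG",         # places UAA at 173 (frame 2: stop after the shift)
    "GGA"
  )
  tx <- transcript("nf2_like", seq)
  stopifnot(codon_at(tx, 6) == "AUG", codon_at(tx, 18) == "AUG",
            codon_at(tx, 60) == "AUG",
            next_in_frame_stop(tx, 9, 0L) == 45,
            next_in_frame_stop(tx, 63, 0L) == 168,
            identical(find_start_sites(tx, "AUG")$position,
                      c(6L, 18L, 60L)))
  events <- list(
    initiation_event(6, "AUG", probability = 0.25),
    initiation_event(18, "AUG", probability = 1.0),
    initiation_event(60, "AUG")
  )
  list(
    transcript = tx,
    events = events,
    policy = reinitiation_policy(max_translon_nt = 100),
    variant = variant_spec(tx$id, 24L, "", "U"),
    cds_translon = "T3"
  )
}

#' Write a fixture to disk
#'
#' Writes the FASTA sequence, the BED6-like event file, the policy as YAML
#' and, when present, the canonical branch probabilities as JSON, under
#' `dir` with the fixture name as basename.
#'
#' @param fixture a list from one of the [fixtures] constructors.
#' @param name basename for the files.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture <- function(fixture, name, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(fasta = file.path(dir, paste0(name, ".fa")),
             events = file.path(dir, paste0(name, ".events.bed")),
             policy = file.path(dir, paste0(name, ".policy.yaml")))
  write_fasta(list(fixture$transcript), files[["fasta"]])
  write_events(fixture$events, fixture$transcript$id, files[["events"]])
  yaml::write_yaml(unclass(fixture$policy), files[["policy"]])
  if (!is.null(fixture$probs)) {
    files[["probs"]] <- file.path(dir, paste0(name, ".probs.json"))
    jsonlite::write_json(as.list(fixture$probs), files[["probs"]],
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(fixture$variant)) {
    files[["variants"]] <- file.path(dir, paste0(name, ".variants.tsv"))
    write_variants(list(fixture$variant), files[["variants"]])
  }
  invisible(files)
}
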