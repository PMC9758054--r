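# Shared fixtures: a 450-bp unzipping segment with promoter, A20 stall site
# and a dCas target (protospacer + PAM) ~300 bp downstream of the stall, in
# both unzip orientations. Sequences are generated from a fixed seed so all
# fixtures are reproducible without stored data files.

fixture_sequence <- function(n = 450, seed = 11) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = c(.3, .2, .2, .3)),
          collapse = ""))
}

fixture_construct <- function(direction = c("PAM_distal_first",
                                            "PAM_proximal_first")) {
  direction <- match.arg(direction)
  seq <- fixture_sequence()
  ann <- if (direction == "PAM_distal_first")
    data.frame(
      name = c("promoter", "A20", "protospacer", "PAM", "template_end"),
      start = c(20, 50, 330, 350, 449),
      end = c(40, 51, 350, 353, 450),
      kind = c("promoter", "A20", "protospacer", "PAM", "template_end"))
  else
    data.frame(
      name = c("promoter", "A20", "PAM", "protospacer", "template_end"),
      start = c(20, 50, 330, 333, 449),
      end = c(40, 51, 333, 353, 450),
      kind = c("promoter", "A20", "PAM", "protospacer", "template_end"))
  unzip_construct(seq, arm_bp = 2200, direction = direction,
                  annotations = ann)
}

# theory curves are expensive; compute once per test session
.fixture_cache <- new.env(parent = emptyenv())

fixture_theory <- function(direction = "PAM_distal_first") {
  key <- paste0("theory_", direction)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- unzip_theory(fixture_construct(direction))
  .fixture_cache[[key]]
}

# a homopolymer construct for plateau / work-balance checks
fixture_homopolymer <- function(base = "A", n = 120) {
  ann <- data.frame(name = "end", start = n - 1, end = n,
                    kind = "template_end")
  unzip_construct(paste(rep(base, n), collapse = ""), arm_bp = 2200,
                  direction = "PAM_distal_first", annotations = ann)
}

# random valid generator configuration for property tests
random_generator_config <- function() {
  f <- stats::runif(4, 0.05, 1)
  f <- f / sum(f)
  names(f) <- PRE_CATEGORIES
  prt <- stats::runif(1, 0.05, 0.8)
  prs <- stats::runif(1, 0, 1 - prt - 0.01)
  generator_config(
    f_initial = f,
    p_motor_diss = stats::runif(1, 0, 0.4),
    p_dcas_diss = stats::runif(1, 0, 0.4),
    p_coll_comp = stats::runif(1, 0.2, 1),
    p_read_through = prt, p_removal_stall = prs,
    p_runoff = stats::runif(1))
}

# estimator applied to exact expected fractions of a configuration
estimate_from_expected <- function(cfg) {
  ef <- expected_fractions(cfg)
  cc <- chamber_counts(ef$pre, ef$post, counts = FALSE)
  nu <- nuisance_params(cfg$p_motor_diss, cfg$p_dcas_diss)
  p_cc <- collision_competence(cc, nu)
  c(p_coll_comp = as.numeric(p_cc),
    p_read_through = read_through(cc, nu, p_cc),
    p_removal = removal(cc, nu, p_cc))
}
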