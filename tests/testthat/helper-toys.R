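# Shared fixtures: closed-form toy instances and random-instance generators.

long_panel <- function(values) {
  # values: named list dmu -> named list variable -> value (single period,
  # single division "unit")
  rows <- lapply(names(values), function(d)
    data.frame(dmu = d, period = "p1", division = "unit",
               variable = names(values[[d]]),
               value = unlist(values[[d]]), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Toy-A: one input, one good output; B uses twice A's input for the same
# output, so B's only inefficiency is input excess: theta(B) = 1 - 1/2 = 0.5
toy_a <- function() {
  spec <- dea_spec(list(unit = list(inputs = "x", good_outputs = "y")))
  df <- long_panel(list(A = list(x = 1, y = 1), B = list(x = 2, y = 1)))
  list(spec = spec, panel = dea_panel(df, spec))
}

# Toy-B: adds a bad output; B emits twice A's bad output:
# theta(B) = 1 / (1 + (1/2) * (1/2)) = 0.8
toy_b <- function() {
  spec <- dea_spec(list(unit = list(inputs = "x", good_outputs = "y",
                                    bad_outputs = "b")))
  df <- long_panel(list(A = list(x = 1, y = 1, b = 1),
                        B = list(x = 1, y = 1, b = 2)))
  list(spec = spec, panel = dea_panel(df, spec))
}

# random single-division instance inside the oracle domain
# (n <= 3, T <= 2, at most one carry-over, values in [1, 10])
random_oracle_instance <- function(seed) {
  set.seed(seed)
  n <- sample(2:3, 1)
  Tn <- sample(1:2, 1, prob = c(0.7, 0.3))
  m <- sample(1:2, 1)
  r1 <- sample(1:2, 1)
  r2 <- sample(0:1, 1)
  ng <- if (Tn == 2) 1L else sample(0:1, 1)
  div <- list(unit = list(
    inputs = paste0("x", seq_len(m)),
    good_outputs = paste0("y", seq_len(r1)),
    bad_outputs = if (r2) paste0("b", seq_len(r2)) else NULL))
  co <- if (ng) data.frame(division = "unit", variable = "z",
                           stringsAsFactors = FALSE) else NULL
  spec <- dea_spec(div, carryovers = co)
  vars <- c(div$unit$inputs, div$unit$good_outputs, div$unit$bad_outputs,
            if (ng) "z")
  dmus <- LETTERS[seq_len(n)]
  periods <- paste0("p", seq_len(Tn))
  df <- expand.grid(dmu = dmus, period = periods, variable = vars,
                    stringsAsFactors = FALSE)
  df$division <- "unit"
  df$value <- round(runif(nrow(df), 1, 10), 3)
  list(spec = spec, panel = dea_panel(df, spec, periods = periods),
       n = n, Tn = Tn)
}

# random multi-division dynamic panel for property tests (small n)
random_network_panel <- function(seed, n = 4, Tn = 2) {
  set.seed(seed)
  spec <- dea_spec(
    divisions = list(
      s1 = list(inputs = c("x1", "x2"), good_outputs = "y1"),
      s2 = list(inputs = "x3", good_outputs = "y2", bad_outputs = "b1")),
    links = data.frame(source = "s1", target = "s2", variable = "lnk",
                       stringsAsFactors = FALSE),
    carryovers = data.frame(division = "s1", variable = "z",
                            stringsAsFactors = FALSE))
  sv <- dndea:::spec_variables(spec)
  dmus <- paste0("d", seq_len(n))
  periods <- paste0("p", seq_len(Tn))
  df <- do.call(rbind, lapply(seq_len(nrow(sv)), function(i)
    data.frame(dmu = rep(dmus, Tn), period = rep(periods, each = n),
               division = sv$division[i], variable = sv$variable[i],
               value = round(runif(n * Tn, 1, 10), 3),
               stringsAsFactors = FALSE)))
  list(spec = spec, panel = dea_panel(df, spec, periods = periods))
}

minimal_spec <- function() {
  dea_spec(list(unit = list(inputs = "x", good_outputs = "y")))
}
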