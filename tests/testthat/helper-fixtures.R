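# Small in-code fixtures shared across test files.

tiny_schema <- function() {
  trait_schema(list(
    Size = c("Size.1", "Size.2", "Size.3"),
    Feeding = c("Feeding.1", "Feeding.2"),
    Velocity = c("Velocity.1", "Velocity.2", "Velocity.3", "Velocity.4")))
}

# A small fuzzy table over tiny_schema(), including an all-zero Velocity
# block for taxon "b".
tiny_traits <- function() {
  fuzzy_trait_table(
    taxon = c("a", "a", "a", "a", "a",
              "b", "b",
              "c", "c", "c"),
    trait_code = c("Size.1", "Size.2", "Feeding.1", "Velocity.1", "Velocity.2",
                   "Size.3", "Feeding.2",
                   "Size.1", "Feeding.1", "Velocity.4"),
    affinity = c(3, 1, 5, 2, 2,
                 4, 3,
                 1, 2, 5),
    schema = tiny_schema())
}

null_design <- function() {
  generate_design(3, organic = c("macroalgae", "ranunculus", "sparganium"),
                  mineral = character(0), replicates = 3)
}

null_config <- function(phi = 1) {
  generator_config(delta = 0, phi = phi, affinity_sd = 0)
}
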