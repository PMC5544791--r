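grouping_feature,trait,code
Maximum potential size,<=0.25 cm,Size.1
Maximum potential size,>0.25-0.5 cm,Size.2
Maximum potential size,>0.5-1 cm,Size.3
Maximum potential size,>1-2 cm,Size.4
Maximum potential size,>2-4 cm,Size.5
Maximum potential size,>4-8 cm,Size.6
Maximum potential size,>8 cm,Size.7
Life-cycle duration,<=1 year,Life-cycle.1
Life-cycle duration,>1 year,Life-cycle.2
Voltinism,<1,Voltinism.1
Voltinism,1,Voltinism.2
Voltinism,>1,Voltinism.3
Aquatic stages,Egg,Stage.1
Aquatic stages,Larva,Stage.2
Aquatic stages,Nymph,Stage.3
Aquatic stages,Adult,Stage.4
Reproduction strategy,Ovoviviparity,Reproduction.1
Reproduction strategy,"Isolated, free eggs",Reproduction.2
Reproduction strategy,"Isolated, cemented eggs",Reproduction.3
Reproduction strategy,"Clutches, cemented",Reproduction.4
Reproduction strategy,"Clutches, free",Reproduction.5
Reproduction strategy,"Clutches, in vegetation",Reproduction.6
Reproduction strategy,"Clutches, terrestrial",Reproduction.7
Reproduction strategy,Asexual,Reproduction.8
Dispersal strategy,Aquatic passive,Dispersal.1
Dispersal strategy,Aquatic active,Dispersal.2
Dispersal strategy,Aerial passive,Dispersal.3
Dispersal strategy,Aerial active,Dispersal.4
Resistance form,Eggs/statoblasts,Resistance.1
Resistance form,Cocoons,Resistance.2
Resistance form,Housings against desiccation,Resistance.3
Resistance form,Diapause/dormancy,Resistance.4
Resistance form,None,Resistance.5
Respiration method,Tegument,Respiration.1
Respiration method,Gill,Respiration.2
Respiration method,Plastron,Respiration.3
Respiration method,Spiracle,Respiration.4
Respiration method,Hydrostatic vesicle,Respiration.5
Locomotion and substrate relation,Flier,Locomotion.1
Locomotion and substrate relation,Surface swimmer,Locomotion.2
Locomotion and substrate relation,Full water swimmer,Locomotion.3
Locomotion and substrate relation,Crawler,Locomotion.4
Locomotion and substrate relation,Burrower,Locomotion.5
Locomotion and substrate relation,Interstitial,Locomotion.6
Locomotion and substrate relation,Temporarily attached,Locomotion.7
Locomotion and substrate relation,Permanently attached,Locomotion.8
Food consumed,Microorganisms,Food.1
Food consumed,Detritus <1 mm,Food.2
Food consumed,Dead plant >=1 mm,Food.3
Food consumed,Living microphytes,Food.4
Food consumed,Living macrophytes,Food.5
Food consumed,Dead animal >=1 mm,Food.6
Food consumed,Living microinvertebrates,Food.7
Food consumed,Living macroinvertebrates,Food.8
Food consumed,Vertebrates,Food.9
Feeding group,Absorber,Feeding.1
Feeding group,Deposit feeder,Feeding.2
Feeding group,Shredder,Feeding.3
Feeding group,Scraper,Feeding.4
Feeding group,Filter-feeder,Feeding.5
Feeding group,Piercer,Feeding.6
Feeding group,Predator,Feeding.7
Feeding group,Parasite,Feeding.8
Substrate preference,Coarse substrates,Substrate.1
Substrate preference,Gravel,Substrate.2
Substrate preference,Sand,Substrate.3
Substrate preference,Silt,Substrate.4
Substrate preference,Macrophytes,Substrate.5
Substrate preference,Microphytes,Substrate.6
Substrate preference,Twigs/roots,Substrate.7
Substrate preference,Organic detritus,Substrate.8
Substrate preference,Mud,Substrate.9
Velocity preference,Null,Velocity.1
Velocity preference,Slow,Velocity.2
Velocity preference,Medium,Velocity.3
Velocity preference,Fast,Velocity.4
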