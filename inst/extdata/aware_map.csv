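drug,category
Amoxicillin,Access
Ampicillin,Access
Benzylpenicillin,Access
Phenoxymethylpenicillin,Access
Penicillin V,Access
Flucloxacillin,Access
Co-amoxiclav,Access
Amoxicillin/clavulanic acid,Access
Pivmecillinam,Access
Nitrofurantoin,Access
Trimethoprim,Access
Co-trimoxazole,Access
Sulfamethoxazole/trimethoprim,Access
Doxycycline,Access
Tetracycline,Access
Oxytetracycline,Access
Metronidazole,Access
Gentamicin,Access
Clindamycin,Access
Chloramphenicol,Access
Cefalexin,Access
Cefazolin,Access
Cefaclor,Watch
Cefuroxime,Watch
Ceftriaxone,Watch
Clarithromycin,Watch
Azithromycin,Watch
Erythromycin,Watch
Ciprofloxacin,Watch
Levofloxacin,Watch
Moxifloxacin,Watch
Ofloxacin,Watch
Norfloxacin,Watch
Lymecycline,Watch
Minocycline,Watch
Vancomycin,Watch
Teicoplanin,Watch
Fosfomycin,Watch
Rifampicin,Watch
Fusidic acid,Watch
Colistimethate sodium,Reserve
Colistin,Reserve
Linezolid,Reserve
Cefiderocol,Reserve
Methenamine hippurate,Unclassified
Rifaximin,Unclassified
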