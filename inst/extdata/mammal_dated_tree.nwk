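((((((((((Hosa:6.4,Patr:6.4)Hominini:2.4,Gogo:8.8)Homininae:6.9,Poab:15.7)Hominidae:4.9,Nole:20.6)Hominoidea:8.6,(Mamu:11.5,Chae:11.5)Cercopithecoidea:17.7)Catarrhini:13.4,Caja:42.6)Simiiformes:51.8,((Mumu:20.9,Rano:20.9)Murinae:61.2,Orcu:82.1)Glires:12.3)Euarchontoglires:3.1,(((Cafa:22.1,Aime:22.1)Carnivora:56.0,Eqca:78.1)Zooamata:3.6,(Bota:62.4,Susc:62.4)Artiodactyla:19.3)Laurasiatheria:15.8)Boreoeutheria:7.2,Loaf:104.7)Placentalia:59.2,Modo:163.9)Theria;
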